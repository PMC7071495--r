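label,x,y,z,mx,my,mz,p,peak_ms,width_ms,condition
precuneus,0,-0.666666666666667,0.5,0,-0.8,0.6,1,150,100,target
supramarginal_L,-0.611111111111111,-0.444444444444444,0.333333333333333,-0.739940073395944,-0.53813823519705,0.403603676397787,1,250,100,target
middle_frontal_R,0.377777777777778,0.533333333333333,0.133333333333333,0.566352113954854,0.799555925583324,0.199888981395831,1,350,100,target
insula_R,0.422222222222222,0,0.0555555555555556,0.991454295542544,0,0.130454512571387,1,450,100,target
thalamus_MD_R,0.0444444444444444,-0.166666666666667,0.0888888888888889,0.229039333725547,-0.858897501470802,0.458078667451095,1,550,100,target
caudate_body_R,0.155555555555556,0.0222222222222222,0.177777777777778,0.655610068107186,0.0936585811581694,0.749268649265355,1,650,100,target
middle_temporal_R,0.555555555555556,-0.666666666666667,0.0555555555555556,0.63887656499994,-0.766651877999928,0.063887656499994,1,250,100,distractor
claustrum_L,-0.355555555555556,0.0222222222222222,0.0222222222222222,-0.996116490183504,0.062257280636469,0.062257280636469,1,550,100,distractor
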