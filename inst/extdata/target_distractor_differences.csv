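electrode,bin,bin_start_ms,bin_end_ms,diff_uv,flag
F3,1,0,100,-0.142,
F3,2,100,200,1.280,T
F3,3,200,300,0.809,T
F3,4,300,400,-1.198,T
F3,5,400,500,-3.855,T
F3,6,500,600,-2.266,T
F3,7,600,700,-0.686,
Fz,1,0,100,1.298,T
Fz,2,100,200,1.997,T
Fz,3,200,300,2.275,T
Fz,4,300,400,-0.101,
Fz,5,400,500,-0.109,
Fz,6,500,600,-0.876,D
Fz,7,600,700,-1.781,D
F4,1,0,100,-0.550,
F4,2,100,200,2.962,T
F4,3,200,300,-1.617,T
F4,4,300,400,-0.024,
F4,5,400,500,2.493,T
F4,6,500,600,1.017,T
F4,7,600,700,0.800,T
T7,1,0,100,-1.644,T
T7,2,100,200,-4.249,T
T7,3,200,300,0.095,
T7,4,300,400,-1.375,T
T7,5,400,500,-0.568,
T7,6,500,600,1.067,T
T7,7,600,700,-0.782,
Cz,1,0,100,0.805,T
Cz,2,100,200,2.976,T
Cz,3,200,300,0.436,
Cz,4,300,400,0.371,
Cz,5,400,500,2.356,T
Cz,6,500,600,3.061,T
Cz,7,600,700,1.074,T
T8,1,0,100,1.240,T
T8,2,100,200,-0.646,
T8,3,200,300,-0.946,D
T8,4,300,400,-0.148,
T8,5,400,500,-1.806,T
T8,6,500,600,-0.749,
T8,7,600,700,0.753,
P7,1,0,100,1.366,T
P7,2,100,200,-0.106,
P7,3,200,300,-2.172,D
P7,4,300,400,-1.772,D
P7,5,400,500,2.118,T
P7,6,500,600,0.870,T
P7,7,600,700,0.822,T
Pz,1,0,100,-2.256,T
Pz,2,100,200,0.993,T
Pz,3,200,300,2.139,T
Pz,4,300,400,-2.181,T
Pz,5,400,500,-3.538,T
Pz,6,500,600,1.241,T
Pz,7,600,700,3.268,T
P8,1,0,100,-2.720,T
P8,2,100,200,-1.200,T
P8,3,200,300,-0.526,
P8,4,300,400,-0.620,
P8,5,400,500,0.293,
P8,6,500,600,2.100,T
P8,7,600,700,0.846,T
O1,1,0,100,-0.882,T
O1,2,100,200,2.402,T
O1,3,200,300,2.020,T
O1,4,300,400,0.147,
O1,5,400,500,-0.059,
O1,6,500,600,-0.677,
O1,7,600,700,-0.314,
Oz,1,0,100,-0.045,
Oz,2,100,200,0.060,
Oz,3,200,300,0.561,
Oz,4,300,400,0.388,
Oz,5,400,500,-2.287,T
Oz,6,500,600,-2.029,T
Oz,7,600,700,-1.690,T
O2,1,0,100,1.196,T
O2,2,100,200,-2.431,T
O2,3,200,300,-1.358,T
O2,4,300,400,1.062,T
O2,5,400,500,0.729,
O2,6,500,600,-0.742,
O2,7,600,700,-1.466,T
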