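name,x,y,z
Fp1,0.950623,0.288907,-0.113349
Fp2,0.954644,-0.275236,-0.113575
F7,0.623749,0.761836,-0.174765
F3,0.736422,0.546437,0.398859
Fz,0.769834,0.005618,0.638219
F4,0.746922,-0.543550,0.382962
F8,0.630188,-0.756016,-0.176929
T3,-0.003089,0.986255,-0.165200
C3,0.046254,0.743209,0.667459
Cz,0.068901,0.004742,0.997612
C4,0.054735,-0.747494,0.662010
T4,0.008568,-0.985692,-0.168339
T5,-0.616666,0.783263,-0.078887
P3,-0.647405,0.553184,0.524265
Pz,-0.643629,0.005214,0.765320
P4,-0.640406,-0.558885,0.526809
T6,-0.619733,-0.780685,-0.080384
O1,-0.953617,0.298497,0.038903
O2,-0.956922,-0.287745,0.038769
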