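region,hemisphere,brodmann,x,y,z
angular_gyrus,L,BA39,-48,-60,30
angular_gyrus,R,BA39,48,-60,30
dlpfc_ba9,L,BA9,-40,35,30
dlpfc_ba9,R,BA9,40,35,30
dlpfc_ba46,L,BA46,-45,40,18
dlpfc_ba46,R,BA46,45,40,18
pars_triangularis,L,BA45,-50,25,10
pars_triangularis,R,BA45,50,25,10
supramarginal_gyrus,L,BA40,-55,-40,30
supramarginal_gyrus,R,BA40,55,-40,30
middle_temporal_gyrus,L,BA21,-58,-20,-10
middle_temporal_gyrus,R,BA21,58,-20,-10
superior_temporal_gyrus,L,BA22,-58,-25,5
superior_temporal_gyrus,R,BA22,58,-25,5
somatosensory,L,BA1;BA2;BA3,-45,-25,50
somatosensory,R,BA1;BA2;BA3,45,-25,50
somatosensory_association,L,BA7,-20,-65,55
somatosensory_association,R,BA7,20,-65,55
premotor_sma,L,BA6,-30,0,55
premotor_sma,R,BA6,30,0,55
subcentral,L,BA43,-58,-10,20
subcentral,R,BA43,58,-10,20
inferior_frontal_gyrus,L,BA47,-40,30,-12
inferior_frontal_gyrus,R,BA47,40,30,-12
v3,L,BA19,-35,-85,15
v3,R,BA19,35,-85,15
frontal_eye_fields,L,BA8,-28,25,45
frontal_eye_fields,R,BA8,28,25,45
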