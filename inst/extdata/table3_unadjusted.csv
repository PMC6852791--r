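clinic_id,exposed,n,p_control
A,0,4778,0.3599
A,1,573,0.4122
B,0,6335,0.4027
B,1,2324,0.3901
C,0,11535,0.3419
C,1,3269,0.3713
D,0,3500,0.3067
D,1,2208,0.3446
E,0,1050,0.1570
E,1,229,0.1717
F,0,1160,0.2049
F,1,337,0.2590
All,0,28325,0.3278
All,1,8940,0.3548
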