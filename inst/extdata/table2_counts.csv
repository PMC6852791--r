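variable,level,n_uncontrolled,n_controlled,n_missing
referred,No,63284,31225,33258
referred,Yes,16254,8940,4797
previous_control,No,69031,15161,30918
previous_control,Yes,12707,19724,15628
n_complications,0,77522,36812,40760
n_complications,1,45655,19015,20236
n_complications,>1,21752,7894,8605
risk_factors,No,24358,9576,14853
risk_factors,Yes,120571,54145,54748
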