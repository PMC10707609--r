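method,n,mean,sd,min,max
mrd1_manual,56,2.6404,1.03859,0.83,5.07
mrd1_dl,56,2.8450,1.07324,0.74,5.27
mrd1_ir,56,2.7839,1.07560,1.09,5.70
mrd1_rgb,56,3.0737,0.94669,1.52,5.68
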