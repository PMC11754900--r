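variable,E1,E2,E3,E4,E5
cloud,0.121,0.775,0.017,0.065,-0.110
wind,-0.045,-0.046,0.127,-0.161,0.469
meanTemp,0.489,0.671,0.194,0.071,-0.241
melt,0.268,0.502,0.129,0.040,-0.225
elevation,-0.959,-0.228,-0.078,0.138,0.042
rugosity,-0.038,0.120,-0.039,0.955,-0.121
slope,-0.045,0.082,-0.031,0.965,-0.158
totPrecip,0.071,0.947,0.101,0.140,0.253
solar,0.112,0.147,0.697,-0.051,0.149
DDm5,0.549,0.574,0.171,0.067,-0.036
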