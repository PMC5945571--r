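family,model,n,q2,r2,f,s,intercept,q2_suspect,r2_suspect,s_suspect
QSAR,1,50,0.793,0.828,14.5,0.291,-1.5373,FALSE,FALSE,FALSE
QSAR,2,50,0.7534,0.7873,11.1,0.301,-1.644,TRUE,TRUE,FALSE
QSAR,3,47,0.781,0.881,21.8,0.231,-1.6531,FALSE,FALSE,FALSE
QSAR,4,47,0.759,0.858,21.3,0.234,-1.6723,FALSE,FALSE,FALSE
QSAR,5,39,0.851,0.965,49.2,0.137,-2.80322,FALSE,FALSE,FALSE
QSAR,6,39,0.832,0.957,39.4,0.152,-2.8386,FALSE,FALSE,FALSE
QPAR,1,50,0.759,0.829,20.9,0.293,-0.3266,FALSE,FALSE,FALSE
QPAR,2,50,0.63,0.812,20.2,0.297,-0.3421,FALSE,FALSE,FALSE
QPAR,3,47,0.761,0.88,24.1,0.022,-2.3992,FALSE,FALSE,TRUE
QPAR,4,47,0.751,0.88,23.8,0.021,-2.3891,FALSE,FALSE,TRUE
QPAR,5,39,0.84,0.929,34.3,0.151,7.8613,FALSE,FALSE,FALSE
QPAR,6,39,0.818,0.917,29.6,0.162,4.817,FALSE,FALSE,FALSE
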