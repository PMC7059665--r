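cultivar,features,set,CK_CK,CK_Q,CK_S,Q_CK,Q_Q,Q_S,S_CK,S_Q,S_S,printed_accuracy,printed_kappa
XS134,full_spectrum,train,25,0,0,0,23,3,1,1,26,93.67,90.47
XS134,full_spectrum,validation,6,0,0,0,6,0,0,2,5,89.47,80.65
XS134,full_spectrum,test,5,0,1,0,7,0,1,0,6,90,84.96
ZJ88,full_spectrum,train,28,0,0,0,28,0,0,0,26,100,100
ZJ88,full_spectrum,validation,7,0,0,0,6,1,0,0,6,95,92.51
ZJ88,full_spectrum,test,6,0,0,0,6,0,0,0,7,100,100
XS134,pc10,train,25,0,0,0,21,5,0,2,26,91.14,86.68
XS134,pc10,validation,6,0,0,0,6,0,0,2,5,89.47,80.65
XS134,pc10,test,5,0,1,0,6,1,1,0,6,85,76.15
ZJ88,pc10,train,28,0,0,0,28,0,0,0,26,100,100
ZJ88,pc10,validation,7,0,0,0,6,1,0,0,6,95,92.5
ZJ88,pc10,test,6,0,0,0,6,0,0,2,5,89.47,80.5
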