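timepoint,method,n,mean,sd
1,test,55,2.77,0.46
2,test,55,2.39,0.40
3,test,55,2.57,0.43
4,test,54,2.54,0.48
5,test,54,3.05,0.40
1,reference,55,2.76,0.48
2,reference,55,2.38,0.36
3,reference,55,2.50,0.42
4,reference,54,2.54,0.50
5,reference,54,3.02,0.40
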