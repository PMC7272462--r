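variable,group,mean,sd,n
age,control,27.09,4.308,22
age,mTBI,34.916,6.999,12
age,msTBI,28.300,3.773,10
time_since_injury,mTBI,3.673,1.793,12
time_since_injury,msTBI,2.525,1.602,10
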