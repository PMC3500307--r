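timetree,taxonomy,time_ma,direction
AUTOhard,Groves93,8.0,increase
AUTOhard,Groves93,1.9,decrease
AUTOhard,Groves05,8.0,increase
AUTOhard,Groves05,0.5,decrease
AUTOhard,Groves05+,8.0,increase
AUTOhard,Groves05+,0.5,decrease
AUTOsoft,Groves93,19.8,increase
AUTOsoft,Groves93,8.7,increase
AUTOsoft,Groves93,1.7,decrease
AUTOsoft,Groves05,19.8,increase
AUTOsoft,Groves05,8.1,increase
AUTOsoft,Groves05,0.5,decrease
AUTOsoft,Groves05+,19.8,increase
AUTOsoft,Groves05+,8.5,increase
AUTOsoft,Groves05+,0.5,decrease
IRhard,Groves93,3.4,increase
IRhard,Groves93,0.4,decrease
IRhard,Groves05,6.3,increase
IRhard,Groves05,0.3,decrease
IRhard,Groves05+,6.3,increase
IRhard,Groves05+,0.6,increase
IRhard,Groves05+,0.1,decrease
IRsoft,Groves93,5.7,increase
IRsoft,Groves93,0.3,decrease
IRsoft,Groves05,5.8,increase
IRsoft,Groves05,0.2,decrease
IRsoft,Groves05+,0.5,increase
IRsoft,Groves05+,0.1,decrease
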