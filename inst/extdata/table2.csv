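num,humidity,temperature,ammonia,result,error
1,65.9,20.6,3.0,both,FALSE
2,80.4,19.7,1.0,stool,FALSE
3,63.7,21.1,0.0,stool,FALSE
4,67.0,17.9,7.0,urine,TRUE
5,55.4,19.2,2.0,urine,FALSE
6,76.0,23.4,2.0,urine,FALSE
7,42.0,19.7,3.0,stool,FALSE
8,43.3,19.8,8.0,urine,FALSE
9,22.9,15.1,0.0,none,FALSE
10,52.8,19.6,5.0,urine,FALSE
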