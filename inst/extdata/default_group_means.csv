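strain,pruritogen,dose_fold,mean_bouts,sem,n,source
C57,endothelin,0.3,280,77,8,printed
C57,endothelin,1,745,186,8,synthetic-default
C57,endothelin,3,1168,292,8,synthetic-default
C57,endothelin,10,1633,289,8,printed
C57,chloroquine,0.3,140,35,6,synthetic-default
C57,chloroquine,1,192,28,6,printed
C57,chloroquine,3,513,146,6,printed
C57,chloroquine,10,430,108,6,synthetic-default
C57,trypsin,0.3,160,40,8,synthetic-default
C57,trypsin,1,138,43,8,printed
C57,trypsin,3,334,84,8,synthetic-default
C57,trypsin,10,549,92,8,printed
C57,LPA,0.3,61,17,8,printed
C57,LPA,1,170,43,8,synthetic-default
C57,LPA,3,269,67,8,synthetic-default
C57,LPA,10,378,80,8,printed
C57,histamine,0.3,150,38,6,synthetic-default
C57,histamine,1,260,65,6,synthetic-default
C57,histamine,3,406,37,6,printed
C57,histamine,10,350,88,6,synthetic-default
C57,5-HT,0.3,155,39,8,synthetic-default
C57,5-HT,1,265,66,8,synthetic-default
C57,5-HT,3,409,63,8,printed
C57,5-HT,10,350,88,8,synthetic-default
C57,SLIGRL,0.3,60,15,7,synthetic-default
C57,SLIGRL,1,95,24,7,synthetic-default
C57,SLIGRL,3,140,35,7,synthetic-default
C57,SLIGRL,10,215,60,7,printed
C3H,endothelin,0.3,111,30,7,printed
C3H,endothelin,1,212,53,7,synthetic-default
C3H,endothelin,3,304,76,7,synthetic-default
C3H,endothelin,10,405,82,7,printed
C3H,chloroquine,0.3,60,15,8,synthetic-default
C3H,chloroquine,1,73,17,8,printed
C3H,chloroquine,3,104,26,8,synthetic-default
C3H,chloroquine,10,138,59,8,printed
C3H,trypsin,0.3,40,10,6,synthetic-default
C3H,trypsin,1,45,11,6,synthetic-default
C3H,trypsin,3,55,14,6,synthetic-default
C3H,trypsin,10,106,19,6,printed
C3H,LPA,0.3,35,9,7,synthetic-default
C3H,LPA,1,40,10,7,synthetic-default
C3H,LPA,3,50,13,7,synthetic-default
C3H,LPA,10,78,16,7,printed
C3H,histamine,0.3,19,9,8,printed
C3H,histamine,1,12,3,8,synthetic-default
C3H,histamine,3,10,3,8,synthetic-default
C3H,histamine,10,8,2,8,synthetic-default
C3H,5-HT,0.3,30,8,7,synthetic-default
C3H,5-HT,1,55,19,7,printed
C3H,5-HT,3,40,10,7,synthetic-default
C3H,5-HT,10,25,6,7,synthetic-default
C3H,SLIGRL,0.3,20,5,8,synthetic-default
C3H,SLIGRL,1,30,8,8,synthetic-default
C3H,SLIGRL,3,50,13,8,synthetic-default
C3H,SLIGRL,10,72,13,8,printed
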