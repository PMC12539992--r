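variable,event_exposed,event_unexposed,nonevent_exposed,nonevent_unexposed
no_mg,88,117,264,1316
male,166,39,1065,515
hypertension,107,98,556,1024
diabetes,33,172,201,1379
gem,48,157,134,1446
capecitabine,2,203,2,1578
mtx,4,201,3,1577
s1,23,182,98,1482
vp16,11,194,44,1536
sh,29,176,343,1237
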