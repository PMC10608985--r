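name,column_id,logk,ppb_lit
bromazepam,HSA,0.0973,70
carbamazepine,HSA,0.1984,75
diclofenac,HSA,1.4921,99.5
nicardipine,HSA,0.901,95
nizatidine,HSA,-0.5005,35
piroxicam,HSA,1.3713,99
bromazepam,AGP,0.2027,70
chlorpromazine,AGP,1.5062,98
imipramine,AGP,0.8308,90
nicardipine,AGP,1.1529,95
nizatidine,AGP,-0.5041,35
propranolol,AGP,0.8308,90
warfarin,AGP,1.5062,98
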