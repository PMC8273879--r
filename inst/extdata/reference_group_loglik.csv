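experiment,model,group_logL
exp1,activation,-1277.305
exp1,associative,-1217.662
exp1,reinforcement,-1255.188
exp2,activation,-1433.287
exp2,associative,-1375.635
exp2,reinforcement,-1376.439
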