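subject_id,group,game,trial,choice,reward
fix01,FIX,1,1,2,0
fix01,FIX,1,2,1,0
fix01,FIX,1,3,2,0
fix01,FIX,1,4,2,0
fix01,FIX,2,1,2,0
fix01,FIX,2,2,1,0
fix01,FIX,2,3,2,1
fix01,FIX,2,4,2,1
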