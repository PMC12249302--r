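image_id,gt,tp,fp,fn
169284650,27,27,0,0
169282562,13,13,0,0
169284039,21,20,0,1
169285655,64,62,2,2
168138203,21,20,0,1
168138509,53,49,4,1
169262486,3,3,0,0
168138726,18,16,2,0
169283283,9,8,1,0
169284222,44,43,1,0
168138775,41,41,0,0
169262529,4,4,0,0
168138327,14,14,0,0
169282117,8,6,2,0
169284146,11,11,0,0
169285625,66,65,1,0
169282871,10,10,0,0
169283207,22,22,0,0
169283699,8,7,1,0
169284611,40,40,0,2
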