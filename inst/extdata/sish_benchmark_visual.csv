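image_id,gt,tp,fp,fn
169284650,146,143,3,3
169282562,118,117,1,0
169284039,77,67,4,5
169285655,207,202,5,3
168138203,62,61,0,1
168138509,153,148,4,5
169262486,43,42,0,1
168138726,66,65,1,0
169283283,86,84,0,2
169284222,126,125,2,1
168138775,168,164,4,0
169262529,24,21,3,0
168138327,59,55,4,0
169282117,62,59,2,0
169284146,28,31,0,3
169285625,203,201,4,3
169282871,62,61,1,0
169283207,157,156,1,0
169283699,167,161,7,2
169284611,297,300,0,3
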