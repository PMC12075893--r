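basket,label,y,n,is_new
1,lung,7,24,0
2,breast,4,24,0
3,colorectal,5,24,0
4,renal,9,24,0
5,gastric,3,14,1
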