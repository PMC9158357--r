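patient_id,aneurysm_id,diameter_mm,location,shape,ruptured
1,a1,7.9,PcomA,irregular,no
1,a2,7.6,PcomA,irregular,yes
2,a1,5.3,PcomA,regular,no
2,a2,3.7,PcomA,regular,yes
3,a1,4.5,AcomA,irregular,no
3,a2,4.3,MCA,regular,no
3,a3,10.7,MCA,irregular,yes
4,a1,2.4,PcomA,irregular,no
4,a2,4.8,PcomA,regular,yes
5,a1,4.7,PcomA,irregular,no
5,a2,4.0,PcomA,regular,yes
6,a1,6.9,MCA,irregular,no
6,a2,4.1,MCA,regular,yes
7,a1,7.5,AA,regular,no
7,a2,6.1,AcomA,regular,yes
8,a1,6.1,MCA,irregular,no
8,a2,8.4,ICA,regular,yes
9,a1,7.3,MCA,irregular,no
9,a2,3.7,PcomA,regular,yes
10,a1,4.3,PcomA,regular,no
10,a2,5.3,ICA,regular,yes
11,a1,7.4,AcomA,irregular,no
11,a2,14,ICA,irregular,yes
12,a1,5.1,AcomA,regular,no
12,a2,3.6,MCA,regular,yes
13,a1,5.4,PcomA,regular,no
13,a2,11.6,MCA,regular,yes
14,a1,3.3,ICA,regular,no
14,a2,3,ICA,regular,yes
15,a1,6.8,MCA,irregular,no
15,a2,5.4,PcomA,irregular,no
15,a3,6.7,PcomA,regular,yes
16,a1,7,PcomA,irregular,no
16,a2,5.7,PcomA,irregular,yes
17,a1,2.8,MCA,regular,no
17,a2,7.1,PcomA,irregular,no
17,a3,3,ICA,regular,no
17,a4,6.6,PcomA,irregular,yes
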