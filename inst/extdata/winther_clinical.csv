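patient_id,drug,pfs_months
203,everolimus,60.0+
148,everolimus,11.6
6,everolimus,8.1
117,everolimus,1.9
227,everolimus,1.7
90,everolimus,1.3
83,axitinib,8.8
223,axitinib,7.1
259,axitinib,6.2
25,axitinib,5.3
88,axitinib,2.9
149,trametinib,7.4
100,trametinib,6.6
118,trametinib,3.1
156,afatinib,14.3
235,afatinib,11.3
136,afatinib,0.4
237,fgfr,19.3
247,fgfr,1.6
228,fgfr,0.7
183,anti-PD-1,61.0+
294,anti-PD-1,1.7
270,anti-PD-1,0.9
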