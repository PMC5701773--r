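analyte_id,median_t0,q1_t0,q3_t0,median_t1,q1_t1,q3_t1,p,mean_md,dsi,rcv
glc,4.8,4.5,5.1,4.9,4.6,5.3,0.104,1.5,2.3,13.0
tp,73,70,75,74,72,77,0.001,2.2,1.4,8.0
urea,4.08,3.38,4.75,4.16,3.41,5.04,0.010,2.9,6.1,34.6
crea,73.4,68.9,77.8,71.6,66.3,77.8,0.209,-1.0,3.0,16.9
cysc,0.75,0.71,0.82,0.75,0.72,0.79,0.375,-1.1,2.5,15.3
bt,12,9,15,13,7,15,0.021,5.2,10.9,62.5
chol,4.9,4.2,5.3,4.9,4.3,5.4,0.042,1.2,3.0,17.2
hdl,1.8,1.3,1.9,1.8,1.4,2.0,0.082,1.7,3.7,21.7
ldl,2.6,2.2,2.9,2.5,2.2,2.9,0.129,-1.3,3.9,22.1
tg,1.05,0.79,1.62,1.06,0.75,1.43,0.002,-6.5,10.0,56.0
ua,260,220,290,270,220,290,0.006,2.2,4.3,25.4
hscrp,1.00,0.42,2.27,1.02,0.42,2.13,0.070,-1.7,21.1,117.0
ggt,12,10,17,12,10,18,0.046,2.6,6.7,37.4
ast,22,20,26,24,22,32,0.001,9.2,6.2,37.3
alt,16,13,22,17,12,22,0.418,3.5,9.7,56.3
ld,364,342,394,386,364,418,0.001,5.3,4.3,25.8
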