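analyte_id,display_name,unit,cv_a,cv_i,cv_g
glc,Glucose,mmol/L,1.4,4.5,
tp,Total proteins,g/L,0.9,2.8,
urea,Urea,mmol/L,3.0,12.1,
crea,Creatinine,µmol/L,1.4,6.0,
cysc,Cystatin C,mg/L,0.6,5.5,
bt,Total bilirubin,µmol/L,5.8,21.8,
chol,"Cholesterol, total",mmol/L,1.8,6.0,
hdl,HDL cholesterol,mmol/L,2.8,7.3,
ldl,LDL cholesterol,mmol/L,1.6,7.8,
tg,Triglycerides,mmol/L,3.5,19.9,
ua,Uric acid,µmol/L,3.2,8.6,
hscrp,High-sensitivity C-reactive protein,mg/L,1.3,42.2,
ggt,Gamma-glutamyltransferase,U/L 37 °C,1.5,13.4,
ast,Aspartate aminotransferase,U/L 37 °C,5.5,12.3,
alt,Alanine aminotransferase,U/L 37 °C,6.0,19.4,
ld,Lactate dehydrogenase,U/L 37 °C,3.6,8.6,
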