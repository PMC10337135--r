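# Published relative risks for the 11 BMI-related diseases.
# per5_loglinear rows: RR per 5 kg/m^2 of BMI above the TMREL (22 kg/m^2),
#   matched on sex/age band; extend_age=TRUE clamps ages outside the printed
#   bands to the nearest band, extend_age=FALSE means RR = 1 outside the
#   stated applicability window (liver cancer 35-79 y; breast cancer,
#   women above 60 y; breast cancer in men is outside the window).
# categorical rows: step function of BMI band, sex- and age-invariant.
disease_id,form,sex,age_lo,age_hi,bmi_lo,bmi_hi,rr,rr_low,rr_high,extend_age
chd,per5_loglinear,both,35,59,NA,NA,1.50,1.39,1.62,TRUE
chd,per5_loglinear,both,60,69,NA,NA,1.40,1.32,1.49,TRUE
chd,per5_loglinear,both,70,79,NA,NA,1.31,1.23,1.40,TRUE
chd,per5_loglinear,both,80,89,NA,NA,1.30,1.17,1.45,TRUE
stroke,per5_loglinear,both,35,59,NA,NA,1.76,1.52,2.04,TRUE
stroke,per5_loglinear,both,60,69,NA,NA,1.49,1.34,1.67,TRUE
stroke,per5_loglinear,both,70,79,NA,NA,1.33,1.19,1.48,TRUE
stroke,per5_loglinear,both,80,89,NA,NA,1.10,0.94,1.30,TRUE
hhd,categorical,both,NA,NA,15,25,1.17,0.77,1.76,FALSE
hhd,categorical,both,NA,NA,25,50,2.03,1.75,2.36,FALSE
t2dm,categorical,both,NA,NA,15,25,0.96,0.59,1.55,FALSE
t2dm,categorical,both,NA,NA,25,50,2.16,1.89,2.46,FALSE
ckd,categorical,both,NA,NA,15,25,1.14,0.74,1.77,FALSE
ckd,categorical,both,NA,NA,25,50,1.59,1.27,1.99,FALSE
cirrhosis,categorical,both,NA,NA,15,25,0.73,0.54,1.00,FALSE
cirrhosis,categorical,both,NA,NA,25,50,1.79,1.54,2.08,FALSE
colorectal_cancer,per5_loglinear,male,20,89,NA,NA,1.24,1.20,1.28,TRUE
colorectal_cancer,per5_loglinear,female,20,89,NA,NA,1.09,1.05,1.13,TRUE
kidney_cancer,per5_loglinear,male,20,89,NA,NA,1.24,1.20,1.28,TRUE
kidney_cancer,per5_loglinear,female,20,89,NA,NA,1.09,1.05,1.13,TRUE
liver_cancer,per5_loglinear,both,35,79,NA,NA,1.47,1.26,1.71,FALSE
breast_cancer,per5_loglinear,female,61,89,NA,NA,1.12,1.08,1.16,FALSE
pancreatic_cancer,per5_loglinear,both,20,89,NA,NA,1.10,1.07,1.14,TRUE
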