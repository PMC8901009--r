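patient_id,age_years,bmi,total_chol,ldl,hdl,triglycerides,glucose,creatinine,systolic_bp,crp,gender_male,family_history,smoking_current,smoking_past,diabetes,dyslipidemia,hypertension,metabolic_syndrome,obesity,statins
S0001,55.54,27.14,178.92,99.05,31.06,102.43,90.87,0.48,147.29,1.35,Yes,Yes,No,Yes,No,No,No,No,No,Yes
S0002,62.13,22.53,194.04,129.56,51.29,92.76,88.27,0.56,131.68,0.73,No,Yes,No,No,No,Yes,Yes,,No,No
S0003,61.12,34.4,229.15,108.78,36.09,348.3,78.08,0.71,133.46,1.38,Yes,No,,No,No,Yes,Yes,No,Yes,Yes
S0004,70.83,28.79,188.97,97.67,53.68,97.44,83.99,0.75,117.27,1.74,Yes,Yes,No,No,,Yes,Yes,No,,No
S0005,55.29,27.11,125.72,77.31,33.06,89.01,132.22,0.73,116.32,1.53,,No,No,,No,Yes,No,No,,No
S0006,52.49,32.04,272.2,142.57,48.65,146.54,84.64,0.7,140.22,4.52,No,Yes,Yes,No,No,,Yes,No,No,Yes
S0007,66.65,26.88,216.73,122.79,40.97,194.76,106.43,0.81,117.3,1.03,No,No,,No,No,Yes,No,No,No,
S0008,62.48,27.62,86.79,51.54,34.29,110.78,84.71,0.99,122.99,1.07,Yes,Yes,No,No,No,No,,No,No,No
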