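# note: synthetic 25-subject demonstration trial generated by wcesurv's renewal simulator
# seed: 20260925
# followup_days: 30
subject_id,arm,time,event_type
control01,control,28.02,DTH
control02,control,3.55,REMI
control02,control,4.48,REMI
control02,control,4.82,CHF
control02,control,20.3,CHF
control03,control,7.82,DTH
control04,control,30,NONE
control05,control,12.67,CHF
control05,control,18.67,CHF
control05,control,25.72,DTH
control06,control,30,NONE
control07,control,8.39,CHF
control07,control,16.47,REMI
control08,control,10.92,REMI
control09,control,0.01,CHF
control09,control,0.78,CHF
control09,control,1.36,SHK
control09,control,14.33,CHF
control10,control,1.96,CHF
control10,control,3.9,CHF
control11,control,7.45,SHK
control11,control,25.58,REMI
control11,control,25.69,SHK
control12,control,6.97,CHF
treatment01,treatment,11.28,REMI
treatment01,treatment,11.99,CHF
treatment02,treatment,24.87,DTH
treatment03,treatment,17.67,REMI
treatment03,treatment,22.8,DTH
treatment04,treatment,27.07,REMI
treatment04,treatment,27.55,REMI
treatment05,treatment,5.33,CHF
treatment05,treatment,9.81,REMI
treatment06,treatment,8.2,REMI
treatment06,treatment,13.35,REMI
treatment06,treatment,17.52,REMI
treatment06,treatment,23.48,REMI
treatment06,treatment,24.23,DTH
treatment07,treatment,30,NONE
treatment08,treatment,3.62,SHK
treatment09,treatment,1.76,REMI
treatment09,treatment,5.27,SHK
treatment09,treatment,13.2,CHF
treatment09,treatment,18.24,CHF
treatment09,treatment,19.24,SHK
treatment09,treatment,20.31,SHK
treatment09,treatment,22.6,CHF
treatment09,treatment,23.59,SHK
treatment10,treatment,30,NONE
treatment11,treatment,15.63,CHF
treatment12,treatment,30,NONE
treatment13,treatment,6.94,REMI
treatment13,treatment,18.28,DTH
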