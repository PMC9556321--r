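study_id,outcome,ref_lower,ref_upper,alt_lower,alt_upper,measure_type,effect,ci_lower,ci_upper,sample_size,events,followup_years,cv_incidence
cohort_a,ischemic_stroke,0,50,50,100,RR,0.90,0.80,1.01,25000,310,12.5,1
cohort_a,ischemic_stroke,0,50,100,180,RR,0.85,0.74,0.97,25000,290,12.5,1
cohort_a,ischemic_stroke,0,50,180,320,RR,0.80,0.68,0.94,25000,260,12.5,1
cohort_b,ischemic_stroke,0,60,60,140,HR,0.88,0.77,1.00,54000,410,9.8,0
cohort_b,ischemic_stroke,0,60,140,260,HR,0.82,0.69,0.97,54000,350,9.8,0
cohort_b,ischemic_stroke,0,60,260,420,HR,0.78,0.63,0.96,54000,300,9.8,0
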