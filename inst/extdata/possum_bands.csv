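domain,item,kind,grade,low,high,level,res
phys,age,numeric,1,0,60,,1
phys,age,numeric,2,61,70,,1
phys,age,numeric,4,71,Inf,,1
phys,cardiac,categorical,1,,,no_failure,
phys,cardiac,categorical,2,,,cardiac_drugs,
phys,cardiac,categorical,4,,,oedema_warfarin_borderline_cardiomegaly,
phys,cardiac,categorical,8,,,raised_jvp_cardiomegaly,
phys,respiratory,categorical,1,,,no_dyspnoea,
phys,respiratory,categorical,2,,,dyspnoea_on_exertion,
phys,respiratory,categorical,4,,,limiting_dyspnoea,
phys,respiratory,categorical,8,,,dyspnoea_at_rest,
phys,sbp,numeric,8,0,89,,1
phys,sbp,numeric,4,90,99,,1
phys,sbp,numeric,2,100,109,,1
phys,sbp,numeric,1,110,130,,1
phys,sbp,numeric,2,131,170,,1
phys,sbp,numeric,4,171,Inf,,1
phys,pulse,numeric,8,0,39,,1
phys,pulse,numeric,2,40,49,,1
phys,pulse,numeric,1,50,80,,1
phys,pulse,numeric,2,81,100,,1
phys,pulse,numeric,4,101,120,,1
phys,pulse,numeric,8,121,Inf,,1
phys,gcs,numeric,8,3,8,,1
phys,gcs,numeric,4,9,11,,1
phys,gcs,numeric,2,12,14,,1
phys,gcs,numeric,1,15,15,,1
phys,hb,numeric,8,0,9.9,,0.1
phys,hb,numeric,4,10,11.4,,0.1
phys,hb,numeric,2,11.5,12.9,,0.1
phys,hb,numeric,1,13,16,,0.1
phys,hb,numeric,2,16.1,17,,0.1
phys,hb,numeric,4,17.1,18,,0.1
phys,hb,numeric,8,18.1,Inf,,0.1
phys,wcc,numeric,4,0,3,,0.1
phys,wcc,numeric,2,3.1,3.9,,0.1
phys,wcc,numeric,1,4,10,,0.1
phys,wcc,numeric,2,10.1,20,,0.1
phys,wcc,numeric,4,20.1,Inf,,0.1
phys,urea,numeric,1,0,7.5,,0.1
phys,urea,numeric,2,7.6,10,,0.1
phys,urea,numeric,4,10.1,15,,0.1
phys,urea,numeric,8,15.1,Inf,,0.1
phys,sodium,numeric,8,0,125,,1
phys,sodium,numeric,4,126,130,,1
phys,sodium,numeric,2,131,135,,1
phys,sodium,numeric,1,136,Inf,,1
phys,potassium,numeric,8,0,2.8,,0.1
phys,potassium,numeric,4,2.9,3.1,,0.1
phys,potassium,numeric,2,3.2,3.4,,0.1
phys,potassium,numeric,1,3.5,5,,0.1
phys,potassium,numeric,2,5.1,5.3,,0.1
phys,potassium,numeric,4,5.4,5.9,,0.1
phys,potassium,numeric,8,6,Inf,,0.1
phys,ecg,categorical,1,,,normal,
phys,ecg,categorical,4,,,af_rate_60_90,
phys,ecg,categorical,8,,,other_abnormality,
oper,severity,categorical,1,,,minor,
oper,severity,categorical,2,,,moderate,
oper,severity,categorical,4,,,major,
oper,severity,categorical,8,,,major_plus,
oper,multiple,categorical,1,,,one,
oper,multiple,categorical,4,,,two,
oper,multiple,categorical,8,,,more_than_two,
oper,blood_loss,numeric,1,0,100,,1
oper,blood_loss,numeric,2,101,500,,1
oper,blood_loss,numeric,4,501,999,,1
oper,blood_loss,numeric,8,1000,Inf,,1
oper,soiling,categorical,1,,,none,
oper,soiling,categorical,2,,,serous_fluid,
oper,soiling,categorical,4,,,local_pus,
oper,soiling,categorical,8,,,free_bowel_content_pus_or_blood,
oper,malignancy,categorical,1,,,none,
oper,malignancy,categorical,2,,,primary_only,
oper,malignancy,categorical,4,,,nodal_metastases,
oper,malignancy,categorical,8,,,distant_metastases,
oper,mode,categorical,1,,,elective,
oper,mode,categorical,4,,,emergency_resuscitation_possible,
oper,mode,categorical,8,,,emergency_immediate,
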