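category,label,centre,unit_rate,quantity,multiplicity,lump_sum,note
delivery,Design of materials,shared,44,8,2,,2 associated health professionals x 8 h
delivery,Practitioner folders,shared,8.2,1,170,,118 doctors and 52 nurses
delivery,Patient folders,shared,,,,2975,internal accounting; 513 patients at 5.80
delivery,Hand-outs,shared,,,,446,internal accounting
delivery,Consultation meeting,shared,,,,93,1 health professional x 2 h at 44 plus 5 travel; patient cost excluded
delivery,Focus group meeting consultants,shared,,,,1104,3 consultants x 3 h at 121 plus 5 travel each
delivery,Focus group meeting nurses,shared,,,,411,3 nurses x 3 h at 44 plus 5 travel each
delivery,Preparatory meetings consultants,Cambridge,121,3,200,,2 consultants x 3 h x 100 practice sessions
delivery,Preparatory meetings doctors,Cambridge,121,1.5,450,,4.5 doctors x 1.5 h x 100 practice sessions
delivery,Preparatory meetings practice nurses,Cambridge,30,1.5,200,,2 nurses x 1.5 h x 100 practice sessions
delivery,Structured education sessions,Leicester,,,,3493,2 educators x 6 h x 6 sessions at 44 plus 54.10 logistics x 6
extra_consultations,GP visits 10 min x 3 per year x 3 years,Cambridge,,,,121091,discounted at 3.5 percent per annum
extra_consultations,Nurse visits 10 min x 3 per year x 3 years,Cambridge,,,,19637,discounted at 3.5 percent per annum
extra_consultations,GP initial visit plus extra visits plus annual review,Leicester,,,,28534,discounted at 3.5 percent per annum
extra_consultations,Follow-up visits plus annual reviews,Leicester,,,,20748,discounted at 3.5 percent per annum
extra_treatments,Extra prescriptions of SU and ACE-inhibitors and statins,Cambridge,262.5,1,452,,262.50 per patient
extra_treatments,Extra prescriptions of SU and ACE-inhibitors and statins,Leicester,,,,16013,internal accounting; 262.50 per patient x 61
extra_treatments,Glucometers and test strips,shared,,,,4406,95 percent of participants issued glucometer and 50 strips
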