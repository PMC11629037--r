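name,role,system,code,prefix,description
myopericarditis_dx,target_diagnosis,http://hl7.org/fhir/sid/icd-10-cm,I40,TRUE,Acute myocarditis family
myopericarditis_dx,target_diagnosis,http://hl7.org/fhir/sid/icd-10-cm,I41,FALSE,Myocarditis in diseases classified elsewhere
myopericarditis_dx,target_diagnosis,http://hl7.org/fhir/sid/icd-10-cm,I51.4,FALSE,Myocarditis unspecified
myopericarditis_dx,target_diagnosis,http://hl7.org/fhir/sid/icd-10-cm,I30,TRUE,Acute pericarditis family
myopericarditis_dx,target_diagnosis,http://hl7.org/fhir/sid/icd-10-cm,I31.9,FALSE,Disease of pericardium unspecified
myopericarditis_dx,target_diagnosis,http://hl7.org/fhir/sid/icd-10-cm,I32,FALSE,Pericarditis in diseases classified elsewhere
cardiac_workup,supporting_evidence,http://loinc.org,6598-7,FALSE,Troponin T cardiac mass/volume serum or plasma
cardiac_workup,supporting_evidence,http://loinc.org,10839-9,FALSE,Troponin I cardiac mass/volume serum or plasma
cardiac_workup,supporting_evidence,http://loinc.org,42757-5,FALSE,Troponin I cardiac mass/volume blood
cardiac_workup,supporting_evidence,http://loinc.org,49563-0,FALSE,Troponin I cardiac mass/volume by detection limit 0.01
cardiac_workup,supporting_evidence,http://loinc.org,13969-1,FALSE,Creatine kinase MB mass/volume serum or plasma
covid19_vaccines,exposure_vaccine,http://hl7.org/fhir/sid/cvx,207,FALSE,COVID-19 mRNA LNP-S 100 mcg (Moderna)
covid19_vaccines,exposure_vaccine,http://hl7.org/fhir/sid/cvx,208,FALSE,COVID-19 mRNA LNP-S 30 mcg (Pfizer-BioNTech)
covid19_vaccines,exposure_vaccine,http://hl7.org/fhir/sid/cvx,211,FALSE,COVID-19 subunit rS adjuvanted (Novavax)
covid19_vaccines,exposure_vaccine,http://hl7.org/fhir/sid/cvx,212,FALSE,COVID-19 vector-nr rS-Ad26 (Janssen)
covid19_vaccines,exposure_vaccine,http://hl7.org/fhir/sid/cvx,213,FALSE,COVID-19 vaccine unspecified
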