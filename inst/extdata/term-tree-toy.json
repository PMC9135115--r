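[{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11","display":"Diabetes mellitus, Type 2"},"children":[{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.0","display":"Diabetes mellitus, Type 2: with coma"},"children":[]},{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.1","display":"Diabetes mellitus, Type 2: subtype 1"},"children":[]},{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.2","display":"Diabetes mellitus, Type 2: subtype 2"},"children":[]},{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.3","display":"Diabetes mellitus, Type 2: subtype 3"},"children":[]},{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.4","display":"Diabetes mellitus, Type 2: subtype 4"},"children":[]},{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.5","display":"Diabetes mellitus, Type 2: subtype 5"},"children":[]},{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.6","display":"Diabetes mellitus, Type 2: subtype 6"},"children":[]},{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.7","display":"Diabetes mellitus, Type 2: subtype 7"},"children":[]},{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.8","display":"Diabetes mellitus, Type 2: subtype 8"},"children":[]},{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.9","display":"Diabetes mellitus, Type 2: subtype 9"},"children":[]}]},{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"C50.1","display":"Malignant neoplasm of breast: central portion"},"children":[]},{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/ops","code":"5-787","display":"Removal of osteosynthesis material"},"children":[{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/ops","code":"5-787.0"},"children":[]},{"termCode":{"system":"http://fhir.de/CodeSystem/bfarm/ops","code":"5-787.1"},"children":[]}]},{"termCode":{"system":"http://loinc.org","code":"55782-7","display":"HER2 panel"},"children":[]},{"termCode":{"system":"http://loinc.org","code":"2160-0","display":"Creatinine [Mass/volume] in Serum or Plasma"},"children":[]},{"termCode":{"system":"http://snomed.info/sct","code":"263495000","display":"Gender"},"children":[]}]
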