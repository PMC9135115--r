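[{"key":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11"},"fhirResourceType":"Condition","termCodeSearchParameter":"code","timeRestrictionParameter":"recorded-date"},{"key":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.0"},"fhirResourceType":"Condition","termCodeSearchParameter":"code","timeRestrictionParameter":"recorded-date"},{"key":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.1"},"fhirResourceType":"Condition","termCodeSearchParameter":"code","timeRestrictionParameter":"recorded-date"},{"key":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.2"},"fhirResourceType":"Condition","termCodeSearchParameter":"code","timeRestrictionParameter":"recorded-date"},{"key":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.3"},"fhirResourceType":"Condition","termCodeSearchParameter":"code","timeRestrictionParameter":"recorded-date"},{"key":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.4"},"fhirResourceType":"Condition","termCodeSearchParameter":"code","timeRestrictionParameter":"recorded-date"},{"key":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.5"},"fhirResourceType":"Condition","termCodeSearchParameter":"code","timeRestrictionParameter":"recorded-date"},{"key":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.6"},"fhirResourceType":"Condition","termCodeSearchParameter":"code","timeRestrictionParameter":"recorded-date"},{"key":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.7"},"fhirResourceType":"Condition","termCodeSearchParameter":"code","timeRestrictionParameter":"recorded-date"},{"key":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.8"},"fhirResourceType":"Condition","termCodeSearchParameter":"code","timeRestrictionParameter":"recorded-date"},{"key":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"E11.9"},"fhirResourceType":"Condition","termCodeSearchParameter":"code","timeRestrictionParameter":"recorded-date"},{"key":{"system":"http://fhir.de/CodeSystem/bfarm/icd-10-gm","code":"C50.1"},"fhirResourceType":"Condition","termCodeSearchParameter":"code","timeRestrictionParameter":"recorded-date"},{"key":{"system":"http://fhir.de/CodeSystem/bfarm/ops","code":"5-787"},"fhirResourceType":"Procedure","termCodeSearchParameter":"code","timeRestrictionParameter":"date"},{"key":{"system":"http://fhir.de/CodeSystem/bfarm/ops","code":"5-787.0"},"fhirResourceType":"Procedure","termCodeSearchParameter":"code","timeRestrictionParameter":"date"},{"key":{"system":"http://fhir.de/CodeSystem/bfarm/ops","code":"5-787.1"},"fhirResourceType":"Procedure","termCodeSearchParameter":"code","timeRestrictionParameter":"date"},{"key":{"system":"http://loinc.org","code":"55782-7"},"fhirResourceType":"Observation","termCodeSearchParameter":"code","valueSearchParameter":"value-quantity","timeRestrictionParameter":"date"},{"key":{"system":"http://loinc.org","code":"2160-0"},"fhirResourceType":"Observation","termCodeSearchParameter":"code","valueSearchParameter":"value-quantity","timeRestrictionParameter":"date"},{"key":{"system":"http://snomed.info/sct","code":"263495000"},"fhirResourceType":"Patient","valueSearchParameter":"gender"}]
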