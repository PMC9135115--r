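{
  "version": "fq/v1",
  "inclusionCriteria": [
    [
      {
        "termCodes": [
          {
            "system": "http://fhir.de/CodeSystem/bfarm/icd-10-gm",
            "code": "E11",
            "display": "Diabetes mellitus, Type 2"
          }
        ]
      }
    ]
  ],
  "exclusionCriteria": [
    [
      {
        "termCodes": [
          {
            "system": "http://snomed.info/sct",
            "code": "263495000",
            "display": "Gender"
          }
        ],
        "valueFilter": {
          "type": "concept",
          "selectedConcepts": [
            {
              "system": "http://hl7.org/fhir/administrative-gender",
              "code": "other"
            }
          ]
        }
      }
    ]
  ]
}
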