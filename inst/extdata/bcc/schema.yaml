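# Extraction schema: record-level fields per entity category.
# Kinds: text, number (mm), date (ISO-8601), boolean, clock (1-12).
categories:
  - name: AccessionNumber
    features:
      - {name: accession_number, kind: text}
  - name: ExcisionDate
    features:
      - {name: excision_date, kind: date}
  - name: ClinicalDetails
    features:
      - {name: site, kind: text}
  - name: MacroscopicDetails
    features:
      - {name: specimen_dim1_mm, kind: number}
      - {name: specimen_dim2_mm, kind: number}
      - {name: specimen_dim3_mm, kind: number}
  - name: MicroscopicDetails
    features:
      - {name: tag, kind: text}
      - {name: subtype, kind: text}
      - {name: perineural_invasion, kind: text}
      - {name: lymphovascular_invasion, kind: text}
      - {name: ulceration, kind: text}
      - {name: residual_disease, kind: text}
      - {name: level_of_invasion, kind: text}
      - {name: completeness_of_excision, kind: text}
  - name: MicroscopicMeasurements
    features:
      - {name: tumour_thickness_mm, kind: number}
      - {name: tumour_diameter_mm, kind: number}
      - {name: peripheral_clearance_mm, kind: number}
      - {name: peripheral_clearance_clock, kind: clock}
      - {name: deep_clearance_mm, kind: number}
  - name: ReportDetails
    features:
      - {name: report_date, kind: date}
  - name: Requestor
    features:
      - {name: requestor, kind: text}
  - name: SupplementaryReport
    features:
      - {name: supplementary_tag, kind: text}
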