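# Lookup-anchored entity rules.  Appelt control: longest match wins, ties
# broken by priority then declaration order; a match consumes its region.
phase:
  name: entities
  control: appelt
  input: [Lookup, Token]
rules:
  - name: MeasurementWithClock
    priority: 20
    pattern:
      - {category: Lookup, features: {majorType: measurement_axis}, bind: ax}
      - {category: Token, regex: '^:$', quantifier: optional}
      - {category: Token, regex: '^\d+(\.\d+)?$'}
      - {category: Token, regex: '^(?i)(mm|cm)$'}
      - {category: Token, regex: '^(?i)at$'}
      - {category: Token, regex: '^\d{1,2}$'}
      - {category: Token, regex: '^(?i)o$'}
      - {category: Token, regex: "^'$"}
      - {category: Token, regex: '^(?i)clock$'}
    actions:
      - create:
          category: MicroscopicMeasurements
          span: match
          features:
            axis: {from: ax, feature: minorType}
            text: {from: match, raw: true}
  - name: Measurement
    priority: 10
    pattern:
      - {category: Lookup, features: {majorType: measurement_axis}, bind: ax}
      - {category: Token, regex: '^:$', quantifier: optional}
      - {category: Token, regex: '^\d+(\.\d+)?$'}
      - {category: Token, regex: '^(?i)(mm|cm)$'}
    actions:
      - create:
          category: MicroscopicMeasurements
          span: match
          features:
            axis: {from: ax, feature: minorType}
            text: {from: match, raw: true}
  - name: SpecimenDimensions
    priority: 10
    pattern:
      - {category: Token, regex: '^\d+(\.\d+)?$'}
      - {category: Token, regex: '^(?i)x$'}
      - {category: Token, regex: '^\d+(\.\d+)?$'}
      - {category: Token, regex: '^(?i)x$'}
      - {category: Token, regex: '^\d+(\.\d+)?$'}
      - {category: Token, regex: '^(?i)(mm|cm)$'}
    actions:
      - create:
          category: MacroscopicDetails
          span: match
          features:
            specimen_dimensions: {from: match}
  - name: SubtypeDiagnosis
    priority: 10
    pattern:
      - {category: Lookup, features: {majorType: subtype}, bind: sub}
      - {category: Lookup, features: {majorType: diagnosis}}
    actions:
      - create:
          category: MicroscopicDetails
          span: match
          features:
            subtype: {from: sub}
            tag: bcc
  - name: SupplementaryDiagnosis
    priority: 1
    pattern:
      - {category: Lookup, features: {majorType: diagnosis}}
    actions:
      - create:
          category: SupplementaryReport
          span: match
          features:
            supplementary_tag: bcc
  - name: PrognosticFactor
    priority: 5
    pattern:
      - {category: Lookup, features: {majorType: prognostic}}
    actions:
      - create:
          category: MicroscopicDetails
          span: match
          features:
            factor: {from: match}
  - name: LevelOfInvasion
    priority: 5
    pattern:
      - {category: Lookup, features: {majorType: level}}
    actions:
      - create:
          category: MicroscopicDetails
          span: match
          features:
            level: {from: match}
  - name: Completeness
    priority: 5
    pattern:
      - {category: Lookup, features: {majorType: margin}, bind: mg}
    actions:
      - create:
          category: MicroscopicDetails
          span: match
          features:
            excision: {from: mg, feature: minorType}
  - name: ClinicalSite
    priority: 5
    pattern:
      - {category: Lookup, features: {majorType: laterality}, quantifier: optional}
      - {category: Lookup, features: {majorType: site}}
    actions:
      - create:
          category: ClinicalDetails
          span: match
          features:
            site: {from: match}
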