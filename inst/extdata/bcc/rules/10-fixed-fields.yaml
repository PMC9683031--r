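# Fixed-format fields: accession numbers, dates, requestor.  Date patterns
# deliberately create both ExcisionDate and ReportDetails candidates; section
# attribution keeps the one matching its enclosing section.
phase:
  name: fixedfields
  control: all
  input: [Token]
rules:
  - name: AccessionNumber
    priority: 10
    pattern:
      - {category: Token, regex: '^(?i)sb\d{2}$'}
      - {category: Token, regex: '^/$'}
      - {category: Token, regex: '^\d{5}$'}
    actions:
      - create:
          category: AccessionNumber
          span: match
          features:
            value: {from: match, raw: true}
  - name: ExcisionDateNumeric
    priority: 10
    pattern:
      - {category: Token, regex: '^\d{1,2}$'}
      - {category: Token, regex: '^/$'}
      - {category: Token, regex: '^\d{1,2}$'}
      - {category: Token, regex: '^/$'}
      - {category: Token, regex: '^\d{4}$'}
    actions:
      - create:
          category: ExcisionDate
          span: match
          features:
            value: {from: match, raw: true}
  - name: ExcisionDateMonthName
    priority: 10
    pattern:
      - {category: Token, regex: '^\d{1,2}$'}
      - {category: Token, regex: '^(?i)(january|february|march|april|may|june|july|august|september|october|november|december)$'}
      - {category: Token, regex: '^\d{4}$'}
    actions:
      - create:
          category: ExcisionDate
          span: match
          features:
            value: {from: match, raw: true}
  - name: ReportDateNumeric
    priority: 5
    pattern:
      - {category: Token, regex: '^\d{1,2}$'}
      - {category: Token, regex: '^/$'}
      - {category: Token, regex: '^\d{1,2}$'}
      - {category: Token, regex: '^/$'}
      - {category: Token, regex: '^\d{4}$'}
    actions:
      - create:
          category: ReportDetails
          span: match
          features:
            value: {from: match, raw: true}
  - name: ReportDateMonthName
    priority: 5
    pattern:
      - {category: Token, regex: '^\d{1,2}$'}
      - {category: Token, regex: '^(?i)(january|february|march|april|may|june|july|august|september|october|november|december)$'}
      - {category: Token, regex: '^\d{4}$'}
    actions:
      - create:
          category: ReportDetails
          span: match
          features:
            value: {from: match, raw: true}
  - name: RequestorName
    priority: 5
    pattern:
      - {category: Token, regex: '^(?i)dr$'}
      - {category: Token, regex: '^[A-Z][A-Za-z]+$'}
    actions:
      - create:
          category: Requestor
          span: match
          features:
            name: {from: match}
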