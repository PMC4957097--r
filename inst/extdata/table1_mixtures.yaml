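# Model cytosols: ratio strings are [KCl]:[D-Glc]:[L-Gln].
mixtures:
  - name: M1
    ratio: "5:12:3"
    total_molarity: 1.00
    pH: 7.0
  - name: M1a
    ratio: "0:12:3"
    total_molarity: 0.75
    pH: 7.0
  - name: M1b
    ratio: "5:12:0"
    total_molarity: 0.85
    pH: 7.0
  - name: M1c
    ratio: "5:0:3"
    total_molarity: 0.40
    pH: 7.0
  - name: M2
    ratio: "15:12:3"
    total_molarity: 1.50
    pH: 7.0
  - name: M2a
    ratio: "25:12:3"
    total_molarity: 1.50
    pH: 7.0
  - name: M2b
    ratio: "15:22:3"
    total_molarity: 1.50
    pH: 7.0
  - name: KCl
    molarities:
      KCl: 1.50
    pH: 7.0
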