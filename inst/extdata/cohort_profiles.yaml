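# Default cohort assay profiles. lod entries are in ug/L on the raw assay
# scale; analytes lists use metabolite codes from the constants table.
BIS:
  dilution_variable: specific_gravity
  time_of_day_adjusted: true
  analytes_measured: [MMP, MEP, MiBP, MnBP, MBzP, MEHHP, MEOHP, MECPP, MCPP, BPA, BPS, BPF]
  lod_per_analyte:
    MMP: 0.5
    MEP: 0.5
    MiBP: 0.5
    MnBP: 0.5
    MBzP: 0.5
    MEHHP: 0.5
    MEOHP: 0.5
    MECPP: 0.5
    MCPP: 0.5
    BPA: 0.05
    BPS: 0.02
    BPF: 0.06
HOME:
  dilution_variable: specific_gravity
  time_of_day_adjusted: false
  analytes_measured: [MEP, MiBP, MnBP, MBzP, MEHHP, MEOHP, MECPP, MCPP, BPA]
  lod_per_analyte:
    MEP: 0.6
    MiBP: 0.3
    MnBP: 0.6
    MBzP: 0.3
    MEHHP: 0.7
    MEOHP: 0.7
    MECPP: 0.6
    MCPP: 0.2
    BPA: 0.4
CHILD:
  dilution_variable: specific_gravity
  time_of_day_adjusted: false
  analytes_measured: [MEP, MiBP, MnBP, MBzP, MEHP, MEHHP, MEOHP, MCPP]
  lod_per_analyte:
    MEP: 0.3
    MiBP: 0.2
    MnBP: 0.2
    MBzP: 0.1
    MEHP: 0.3
    MEHHP: 0.2
    MEOHP: 0.2
    MCPP: 0.2
ECHO:
  dilution_variable: creatinine
  time_of_day_adjusted: true
  analytes_measured: [MMP, MEP, MiBP, MnBP, MBzP, MEHP, MEHHP, MEOHP, MECPP, MCPP, BPA, BPS, BPF]
  lod_per_analyte:
    MMP: 0.5
    MEP: 0.6
    MiBP: 0.8
    MnBP: 0.4
    MBzP: 0.3
    MEHP: 0.8
    MEHHP: 0.4
    MEOHP: 0.2
    MECPP: 0.4
    MCPP: 0.4
    BPA: 0.2
    BPS: 0.1
    BPF: 0.2
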