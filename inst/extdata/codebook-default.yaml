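cs_candidate_drg_by_year:
  '2014': O01F
  '2015': O01F
  '2016': O01F
  '2017': O01G
  '2018': O01H
svb_drg_by_year:
  '2014': O60D
  '2015': O60D
  '2016': O60D
  '2017': O60D
  '2018': O60D
cs_all_drg_prefixes: O01
icd_exclusions:
- O32
- O33
- O44
- O64
- O65
- O66
chop_emergency: 74.99*
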