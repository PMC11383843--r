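verbatim,standard
nivolumab,nivolumab
opdivo,nivolumab
pembrolizumab,pembrolizumab
keytruda,pembrolizumab
atezolizumab,atezolizumab
tecentriq,atezolizumab
durvalumab,durvalumab
imfinzi,durvalumab
avelumab,avelumab
ipilimumab,ipilimumab
yervoy,ipilimumab
tremelimumab,tremelimumab
temozolomide,temozolomide
temodar,temozolomide
lomustine,lomustine
carmustine,carmustine
vincristine,vincristine
cisplatin,cisplatin
carboplatin,carboplatin
dexamethasone,dexamethasone
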