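trait,type,description,unit
ZD,tissue,Zooxanthellae (symbiont) density,cells/cm2
TB,tissue,Total tissue biomass,mg/cm2
PB,tissue,Protein biomass,mg/cm2
CH,tissue,Chlorophyll concentration,ug/cm2
SV,morphology,Surface area to volume ratio,1/mm
BD,morphology,Branch density,count/cm2
BW,morphology,Branch width,mm
CW,morphology,Corallite width,mm
SD,skeleton,Skeletal density,g/cm3
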