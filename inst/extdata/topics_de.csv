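code,canonical,variants
N17,Akutes Nierenversagen,Nierenversagen akut|Akutes Nierenversagen Stad. III
N18,Chronische Nierenkrankheit,Nierenkrankheit chronisch|Chron. Nierenkrankheit St. 4
E87,Hyperkaliämie,Hyperkaliämie rezidivierend|Rezidivierende Hyperkaliämie
I10,Arterielle Hypertonie,Hypertonie arteriell|Art. Hypertonie
E11,Diabetes mellitus Typ 2,Diabetes mellitus|Diab. mellitus Typ 2
N04,Nephrotisches Syndrom,Syndrom nephrotisch|Nephrot. Syndrom
I50,Herzinsuffizienz NYHA II,Herzinsuffizienz|Herzinsuffizienz NYHA III
E78,Fettstoffwechselstörung,Fettstoffwechselstörung gemischt|Gemischte Fettstoffwechselstörung
N20,Nephrolithiasis,Nephrolithiasis beidseits|Nephrolithiasis links
M81,Osteoporose,Osteoporose postmenopausal|Osteoporose manifest
D64,Renale Anämie,Anämie renal|Renale Anämie bei Dialyse
G40,Fokale Epilepsie,Epilepsie fokal|Epilepsie
E03,Hypothyreose,Hypothyreose latent|Latente Hypothyreose
F32,Depressive Episode,Episode depressiv|Depressive Episode leicht
B18,Chronische Hepatitis,Hepatitis chronisch|Chron. Hepatitis
K29,Chronische Gastritis,Gastritis chronisch|Gastritis
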