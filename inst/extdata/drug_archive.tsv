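name_variant	drug_class	canonical_name
pembrolizumab	ICI	pembrolizumab
Keytruda	ICI	pembrolizumab
MK-3475	ICI	pembrolizumab
lambrolizumab	ICI	pembrolizumab
pembroluzimab	ICI	pembrolizumab
nivolumab	ICI	nivolumab
Opdivo	ICI	nivolumab
BMS-936558	ICI	nivolumab
ONO-4538	ICI	nivolumab
nivolumb	ICI	nivolumab
ipilimumab	ICI	ipilimumab
Yervoy	ICI	ipilimumab
MDX-010	ICI	ipilimumab
atezolizumab	ICI	atezolizumab
Tecentriq	ICI	atezolizumab
MPDL3280A	ICI	atezolizumab
avelumab	ICI	avelumab
Bavencio	ICI	avelumab
MSB0010718C	ICI	avelumab
durvalumab	ICI	durvalumab
Imfinzi	ICI	durvalumab
MEDI4736	ICI	durvalumab
cemiplimab	ICI	cemiplimab
Libtayo	ICI	cemiplimab
REGN2810	ICI	cemiplimab
camrelizumab	ICI	camrelizumab
AiRuiKa	ICI	camrelizumab
SHR-1210	ICI	camrelizumab
sintilimab	ICI	sintilimab
Tyvyt	ICI	sintilimab
IBI308	ICI	sintilimab
tislelizumab	ICI	tislelizumab
BGB-A317	ICI	tislelizumab
toripalimab	ICI	toripalimab
JS001	ICI	toripalimab
Tuoyi	ICI	toripalimab
bevacizumab	AGI	bevacizumab
Avastin	AGI	bevacizumab
bevacizmab	AGI	bevacizumab
ramucirumab	AGI	ramucirumab
Cyramza	AGI	ramucirumab
IMC-1121B	AGI	ramucirumab
ziv-aflibercept	AGI	ziv-aflibercept
aflibercept	AGI	ziv-aflibercept
Zaltrap	AGI	ziv-aflibercept
axitinib	AGI	axitinib
Inlyta	AGI	axitinib
AG-013736	AGI	axitinib
cabozantinib	AGI	cabozantinib
Cabometyx	AGI	cabozantinib
Cometriq	AGI	cabozantinib
XL184	AGI	cabozantinib
lenvatinib	AGI	lenvatinib
Lenvima	AGI	lenvatinib
E7080	AGI	lenvatinib
sunitinib	AGI	sunitinib
Sutent	AGI	sunitinib
SU11248	AGI	sunitinib
sorafenib	AGI	sorafenib
Nexavar	AGI	sorafenib
BAY 43-9006	AGI	sorafenib
pazopanib	AGI	pazopanib
Votrient	AGI	pazopanib
GW786034	AGI	pazopanib
regorafenib	AGI	regorafenib
Stivarga	AGI	regorafenib
BAY 73-4506	AGI	regorafenib
vandetanib	AGI	vandetanib
Caprelsa	AGI	vandetanib
ZD6474	AGI	vandetanib
apatinib	AGI	apatinib
YN968D1	AGI	apatinib
anlotinib	AGI	anlotinib
AL3818	AGI	anlotinib
fruquintinib	AGI	fruquintinib
Elunate	AGI	fruquintinib
HMPL-013	AGI	fruquintinib
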