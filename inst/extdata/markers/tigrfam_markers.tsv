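accession	symbol
TIGR02013	rpoB
TIGR00168	infC
TIGR01953	nusA
TIGR01169	rplA
TIGR01171	rplB
TIGR03953	rplD
TIGR01066	rplM
TIGR01067	rplN
TIGR01164	rplP
TIGR01024	rplS
TIGR01032	rplT
TIGR01011	rpsB
TIGR01009	rpsC
TIGR01021	rpsE
TIGR01049	rpsJ
TIGR01050	rpsS
TIGR00086	smpB
TIGR00116	tsf
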