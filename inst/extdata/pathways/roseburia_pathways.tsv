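# Pathway requirement definitions for the Roseburia-style profile.
# expression: prefix notation over canonical gene symbols; AND children are
# the "missing gene" units, an OR subtree counts as one unit.
pathway_id	category	min_tier	expression
emp_glycolysis	synthesis	MODERATE	AND(pgi,pfkA,fbaA,tpiA,gap,pgk,gpmI,eno,pyk)
ppp_oxidative	synthesis	MODERATE	AND(zwf,pgl,gnd)
ppp_nonoxidative	synthesis	MODERATE	AND(rpe,rpiB,tktA)
ed_pathway	synthesis	MODERATE	AND(edd,eda)
butyrogenesis	synthesis	MODERATE	AND(thl,bhbD,cro,bcd,etfA,etfB,but)
lactate_fermentation	synthesis	MODERATE	OR(ldhL,ldhD)
pyruvate_to_acetylcoa	synthesis	MODERATE	OR(pflD,AND(porA,porB))
rnf_complex	synthesis	MODERATE	AND(rnfA,rnfB,rnfC,rnfD,rnfE,rnfG)
arabinose_utilization	synthesis	MODERATE	AND(araA,araB,araD)
serine_synthesis	synthesis	MODERATE	AND(serA,serC,OR(serB,thrH,glyA))
histidine_synthesis	synthesis	MODERATE	AND(hisG,hisZ,hisD,hisBd,hisEI,hisF,hisH,hisA,hisC,hisBpx)
thiamine_synthesis	synthesis	MODERATE	AND(OR(thiC,AND(cytX,thiD)),thiD,thiE)
thiamine_salvage	salvage_transport	MODERATE	AND(thiT)
riboflavin_synthesis	synthesis	MODERATE	AND(ribA,ribB,ribD,ribE,ribH)
riboflavin_salvage	salvage_transport	MODERATE	AND(ribU,ribF)
pantothenate_synthesis	synthesis	MODERATE	AND(panB,panC,panD)
pantothenate_salvage	salvage_transport	MODERATE	AND(panT)
pyridoxine_synthesis	synthesis	MODERATE	AND(pdxS,pdxT)
pyridoxine_salvage	salvage_transport	MODERATE	OR(AND(pdxK,pdxY,pdxH),pdxU2)
biotin_synthesis	synthesis	MODERATE	AND(bioA,bioD,bioB)
biotin_salvage	salvage_transport	MODERATE	AND(bioY)
folate_synthesis	synthesis	MODERATE	AND(folE,folB,folK,folP,folC)
folate_salvage	salvage_transport	MODERATE	AND(folT)
niacin_synthesis	synthesis	MODERATE	AND(nadB,nadA,nadC,pncB,OR(pncA,surE))
cobalamin_synthesis	synthesis	MODERATE	AND(cbiA,cbiC,cbiD,cbiF,cbiH,cbiL,cobT,cobS)
cobalamin_salvage	salvage_transport	MODERATE	AND(btuC,btuD,btuF)
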