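code,name,level,aliases,groups
NOR,Northmarch,1,North March|Nordmark,Boreal Belt
SNO,Snowfell,1,Snow Fell|Snofjall,Boreal Belt
TAI,Taigaland,1,Tayga Land,Boreal Belt
MER,Meridia,1,Meridian Coast,Austral Rim
PAM,Pampara,1,Pamparas,Austral Rim
FUE,Fuegora,1,Fire Coast,Austral Rim
ARD,Aridia,1,Arid Interior|Aridía,Dry Core
DUN,Dunelands,1,Dune Lands,Dry Core
STE,Steppewald,1,Steppe Wald,Dry Core
INS,Insulara,1,Isle Insulara,Island Arc
ARC,Arcapelago,1,Arc Apelago,Island Arc
COR,Coralonia,1,Coral Islands,Island Arc
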