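acronym,index,module,has_L4
FRP,1,prefrontal,FALSE
ACAd,2,prefrontal,FALSE
ACAv,3,prefrontal,FALSE
PL,4,prefrontal,FALSE
ILA,5,prefrontal,FALSE
ORBl,6,prefrontal,FALSE
ORBm,7,prefrontal,FALSE
ORBvl,8,prefrontal,FALSE
AId,9,lateral,FALSE
AIp,10,lateral,FALSE
AIv,11,lateral,FALSE
GU,12,lateral,TRUE
VISC,13,lateral,TRUE
TEa,14,lateral,TRUE
PERI,15,lateral,FALSE
ECT,16,lateral,FALSE
MOp,17,somatomotor,FALSE
MOs,18,somatomotor,FALSE
SSp-n,19,somatomotor,TRUE
SSp-bfd,20,somatomotor,TRUE
SSp-ll,21,somatomotor,TRUE
SSp-m,22,somatomotor,TRUE
SSp-ul,23,somatomotor,TRUE
SSp-tr,24,somatomotor,TRUE
SSp-un,25,somatomotor,TRUE
SSs,26,somatomotor,TRUE
VISp,27,visual,TRUE
VISal,28,visual,TRUE
VISam,29,visual,TRUE
VISl,30,visual,TRUE
VISli,31,visual,TRUE
VISpl,32,visual,TRUE
VISpm,33,visual,TRUE
VISpor,34,visual,TRUE
VISrl,35,visual,TRUE
VISa,36,visual,TRUE
AUDd,37,auditory,TRUE
AUDp,38,auditory,TRUE
AUDpo,39,auditory,TRUE
AUDv,40,auditory,TRUE
RSPagl,41,medial,FALSE
RSPd,42,medial,FALSE
RSPv,43,medial,FALSE
ENTl,44,medial,FALSE
ENTm,45,medial,FALSE
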