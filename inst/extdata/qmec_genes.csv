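gene,cycle_group
amyA,C_degradation
apu,C_degradation
cda,C_degradation
chiA,C_degradation
cex,C_degradation
cbhI,C_degradation
xylA,C_degradation
abfA,C_degradation
manB,C_degradation
pgu,C_degradation
lig,C_degradation
mnp,C_degradation
glx,C_degradation
pox,C_degradation
amyX,C_degradation
sga,C_degradation
exg,C_degradation
bglX,C_degradation
naglu,C_degradation
pulA,C_degradation
cbbL_IA,C_fixation
cbbL_IC,C_fixation
cbbM,C_fixation
aclB,C_fixation
accA,C_fixation
mct,C_fixation
frdA,C_fixation
korA,C_fixation
amoA_AOA,N
amoA_AOB,N
hao,N
nxrA,N
narG,N
napA,N
nirK,N
nirS,N
norB,N
nosZ,N
nifH,N
nrfA,N
gdh,N
ureC,N
glnA,N
amiE,N
nasA,N
nirA,N
nrtA,N
hzsB,N
hdh,N
nod,N
phoD,P
phoN,P
phoX,P
ppa,P
ppk,P
ppx,P
phnK,P
phnX,P
pitA,P
pstS,P
appA,P
opd,P
gcd,P
dsrA,S
dsrB,S
aprA,S
soxB,S
sqr,S
sreA,S
cysI,S
asrA,S
16S,16S
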