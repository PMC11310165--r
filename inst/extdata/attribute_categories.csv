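attribute,category
SWC,nutrient_stocks
TC,nutrient_stocks
EC,nutrient_stocks
SOM,nutrient_stocks
TK,nutrient_stocks
RAK,nutrient_stocks
SAK,nutrient_stocks
TP,nutrient_stocks
TN,nutrient_stocks
HN,nutrient_stocks
IP,nutrient_stocks
OP,nutrient_stocks
AP,nutrient_stocks
TS,nutrient_stocks
AS,nutrient_stocks
CN_ratio,nutrient_stocks
BGC,organic_matter_decomposition
BXYS,organic_matter_decomposition
BCL,organic_matter_decomposition
LAP,organic_matter_decomposition
AGC,organic_matter_decomposition
NAG,organic_matter_decomposition
ALP,organic_matter_decomposition
ASF,organic_matter_decomposition
PPO,organic_matter_decomposition
POD,organic_matter_decomposition
C_degradation_copies,microbial_functional_genes
C_fixation_copies,microbial_functional_genes
N_cycling_copies,microbial_functional_genes
P_cycling_copies,microbial_functional_genes
S_cycling_copies,microbial_functional_genes
biomass_16S_copies,microbial_functional_genes
pH,excluded
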