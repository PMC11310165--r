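lineage,group
Cercozoa,consumer
Lobosa,consumer
Ciliophora,consumer
Conosa,consumer
Heterolobosea,consumer
Chlorophyta,phototroph
Ochrophyta,phototroph
Dinoflagellata,phototroph
Apicomplexa,parasite
Peronosporomycetes,parasite
Ichthyosporea,parasite
Hacrobia,photophagotroph
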