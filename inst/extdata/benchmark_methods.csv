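method,dataset,accuracy,macro_f1
upper_bound,JLURM,0.872,0.865
random_subset,JLURM,0.684,0.665
dc,JLURM,0.755,0.748
kip,JLURM,0.739,0.726
lors,JLURM,0.819,0.812
edge,JLURM,0.830,0.817
pds,JLURM,0.837,0.831
only_hc2l,JLURM,0.781,0.763
only_ddg,JLURM,0.690,0.675
cgmdd,JLURM,0.847,0.844
upper_bound,MRNet,0.881,0.871
random_subset,MRNet,0.653,0.634
dc,MRNet,0.758,0.751
kip,MRNet,0.746,0.740
lors,MRNet,0.843,0.833
edge,MRNet,0.854,0.848
pds,MRNet,0.840,0.835
only_hc2l,MRNet,0.774,0.763
only_ddg,MRNet,0.703,0.689
cgmdd,MRNet,0.862,0.857
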