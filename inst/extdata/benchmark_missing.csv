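dataset,missing,drop_only_ddg,drop_cgmdd
JLURM,arterial,8.5,2.7
JLURM,venous,9.4,3.1
JLURM,delayed,9.9,5.8
JLURM,arterial+delayed,16.2,9.2
MRNet,sagittal_t2,15.7,10.3
MRNet,coronal_t1,8.6,3.0
MRNet,axial_pd,10.4,3.6
MRNet,sagittal_t2+coronal_t1,23.7,14.2
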