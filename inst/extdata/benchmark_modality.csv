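dataset,condition,accuracy,macro_f1
JLURM,arterial,0.626,0.638
JLURM,venous,0.765,0.770
JLURM,delayed,0.785,0.791
JLURM,multimodal,0.847,0.844
MRNet,sagittal_t2,0.813,0.821
MRNet,coronal_t1,0.623,0.628
MRNet,axial_pd,0.652,0.659
MRNet,multimodal,0.862,0.857
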