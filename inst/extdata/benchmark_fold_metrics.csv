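group,class,metric,fold1,fold2,fold3,fold4,fold5
regions_10x,cancer,dice,84.4,82.1,83,82.8,82.8
regions_10x,normal_epithelium,dice,1.6,2.3,2.1,2.3,2.3
regions_10x,stroma,dice,81.3,80.2,81,80.8,81
regions_10x,tils_dense,dice,64.8,64,65.3,65.6,65.6
regions_10x,necrosis_debris,dice,64.1,55.6,56.7,57.3,57.1
regions_10x,empty,dice,83.5,83.5,84,84.2,84.3
nuclei_20x,cancer,auroc,96.5,97.2,98,97.4,91.1
nuclei_20x,fibroblast,auroc,90.4,93,91.8,93.5,85.8
nuclei_20x,lymphocyte,auroc,93.3,92.3,93.6,91.9,94.2
nuclei_20x,plasma_cell,auroc,80.9,73.5,88,78.9,85.8
nuclei_20x,debris,auroc,82.8,84.9,80.1,93.9,57.1
nuclei_20x,micro_avg,auroc,91.9,92.2,95.6,93.5,88.9
nuclei_20x,macro_avg,auroc,85.4,83.9,86.3,85.2,75.3
nuclei_20x_unconstrained,micro_avg,auroc,90.5,91.1,95.4,91.9,86.2
nuclei_20x_unconstrained,macro_avg,auroc,84.5,78.1,86.9,81.5,73.1
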