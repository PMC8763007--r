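dataset_key,source,cancer_type,platform,n_cells_after_qc,n_tumor_samples,cells_sorted,n_normal_samples,n_tumor_cells,n_normal_cells,age_available
Gastric,Sathe et al. (PMID: 32060101),Gastric cancer,10x Genomics,44684,8,No,8,30626,14058,Yes
Melanoma_GSE115978,GSE115978,Melanoma,Smart-seq2,5910,31,CD45+ and CD45-,0,5910,0,Yes
Melanoma_GSE72056,GSE72056,Melanoma,Smart-seq2,3883,19,CD45+ and CD45-,0,3883,0,Yes
Uveal_GSE139829,GSE139829,Uveal melanoma,10x Genomics,116752,11,No,0,116752,0,Yes
BC_Qian,Qian et al. (PMID: 32561858),Breast cancer,5'-scRNA-seq,44024,14,No,0,44024,0,Yes
CRC_Qian,Qian et al. (PMID: 32561858),CRC,10x Genomics,44684,7,No,7,30626,14058,Yes
HCC_GSE125449,GSE125449,HCC,10x Genomics,9581,19,No,0,9581,0,Yes
HNSCC_GSE103322,GSE103322,HNSCC,Smart-seq2,4849,18,"CD45-, CD45-/CD90-/CD31-, CD45+, CD45+/CD3+",0,4849,0,No
LC_Qian,Qian et al. (PMID: 32561858),Lung cancer,10x Genomics,93575,7,No,7,66309,27266,Yes
OVC_Qian,Qian et al. (PMID: 32561858),Ovarian cancer,10x Genomics,45114,5,No,2,34469,10645,Yes
Bladder,GSE130001,Bladder cancer,10x Genomics,4077,2,CD45-,0,4077,0,No
Kidney,Young et al. (PMID: 30093597),Kidney,10x Genomics,72394,11,No,11,22476,49918,Yes
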