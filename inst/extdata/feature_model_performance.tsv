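feature	accuracy_pct	accuracy_lo	accuracy_hi	auc	auc_lo	auc_hi
irregular_epithelial_stratification	78.2	67.3	89.1	0.768	0.576	0.930
loss_of_polarity_of_basal_cells	79.3	62.1	93.1	0.722	0.578	0.813
drop_shaped_rete_ridges	86.9	78.7	95.1	0.900	0.814	0.967
increased_number_of_mitotic_figures	81.7	71.7	91.7	0.806	0.671	0.927
premature_keratinization_in_single_cells	96.9	92.2	98.4	0.734	0.544	0.856
loss_of_epithelial_cell_cohesion	98.4	93.4	98.4	0.983	0.948	1.000
abnormal_variation_in_nuclear_size	67.6	51.4	81.1	0.725	0.612	0.818
abnormal_variation_in_nuclear_shape	78.9	65.8	92.1	0.776	0.600	0.923
abnormal_variation_in_cell_size	80.0	68.9	91.1	0.883	0.737	0.993
abnormal_variation_in_cell_shape	88.6	79.5	97.7	0.764	0.646	0.876
increased_nc_ratio	62.5	51.5	79.5	0.742	0.604	0.796
hyperchromasia	65.4	51.9	78.8	0.679	0.587	0.759
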