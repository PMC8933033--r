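cst	prevalence_total_pct	taxon	mean_abundance_pct	prevalence_pct
CST-Ss	11	Streptococcus salivarius	10.43	92
CST-Ss	11	Prevotella jejuni	0.81	41
CST-Ss	11	Rothia mucilaginosa	5.59	92
CST-Ss	11	Staphylococcus epidermidis	0.49	5
CST-Ss	11	Neisseria subflava	0.54	19
CST-Ss	11	Prevotella melaninogenica	3.06	63
CST-Ss	11	Streptococcus mitis	3.51	79
CST-Ss	11	Staphylococcus aureus	1.12	11
CST-Ss	11	Haemophilus influenzae	0.25	9
CST-Ss	11	Prevotella histicola	2.05	51
CST-Ss	11	Pseudomonas aeruginosa	0.75	10
CST-Ss	11	Tetrasphaera japonica	0.21	7
CST-Ss	11	Corynebacterium propinquum	0.08	2
CST-Pj	9	Streptococcus salivarius	2.68	81
CST-Pj	9	Prevotella jejuni	9.11	100
CST-Pj	9	Rothia mucilaginosa	1.1	64
CST-Pj	9	Staphylococcus epidermidis	0	0
CST-Pj	9	Neisseria subflava	2.29	73
CST-Pj	9	Prevotella melaninogenica	8.95	100
CST-Pj	9	Streptococcus mitis	2.52	84
CST-Pj	9	Staphylococcus aureus	0.11	3
CST-Pj	9	Haemophilus influenzae	0.03	1
CST-Pj	9	Prevotella histicola	6.37	95
CST-Pj	9	Pseudomonas aeruginosa	0	0
CST-Pj	9	Tetrasphaera japonica	0.01	1
CST-Pj	9	Corynebacterium propinquum	0	0
CST-Rm	9	Streptococcus salivarius	2.61	69
CST-Rm	9	Prevotella jejuni	0.26	16
CST-Rm	9	Rothia mucilaginosa	28.08	100
CST-Rm	9	Staphylococcus epidermidis	0.21	4
CST-Rm	9	Neisseria subflava	3.02	50
CST-Rm	9	Prevotella melaninogenica	1.4	54
CST-Rm	9	Streptococcus mitis	3.17	66
CST-Rm	9	Staphylococcus aureus	0.76	9
CST-Rm	9	Haemophilus influenzae	0.18	5
CST-Rm	9	Prevotella histicola	0.95	32
CST-Rm	9	Pseudomonas aeruginosa	0.67	7
CST-Rm	9	Tetrasphaera japonica	0.13	8
CST-Rm	9	Corynebacterium propinquum	0.03	1
CST-Se	7	Streptococcus salivarius	1.09	23
CST-Se	7	Prevotella jejuni	0.03	4
CST-Se	7	Rothia mucilaginosa	0.65	18
CST-Se	7	Staphylococcus epidermidis	50.12	100
CST-Se	7	Neisseria subflava	0.17	7
CST-Se	7	Prevotella melaninogenica	0.09	7
CST-Se	7	Streptococcus mitis	1.46	30
CST-Se	7	Staphylococcus aureus	2.7	29
CST-Se	7	Haemophilus influenzae	0.57	18
CST-Se	7	Prevotella histicola	0.03	2
CST-Se	7	Pseudomonas aeruginosa	0.9	25
CST-Se	7	Tetrasphaera japonica	1.92	41
CST-Se	7	Corynebacterium propinquum	0.24	5
CST-Ns	6	Streptococcus salivarius	1.17	48
CST-Ns	6	Prevotella jejuni	1.78	65
CST-Ns	6	Rothia mucilaginosa	3.8	96
CST-Ns	6	Staphylococcus epidermidis	0	0
CST-Ns	6	Neisseria subflava	9.26	100
CST-Ns	6	Prevotella melaninogenica	6.53	100
CST-Ns	6	Streptococcus mitis	3.5	87
CST-Ns	6	Staphylococcus aureus	0.07	4
CST-Ns	6	Haemophilus influenzae	0.02	2
CST-Ns	6	Prevotella histicola	1.17	52
CST-Ns	6	Pseudomonas aeruginosa	0	0
CST-Ns	6	Tetrasphaera japonica	0.13	8
CST-Ns	6	Corynebacterium propinquum	0	0
CST-Pm	6	Streptococcus salivarius	2.89	63
CST-Pm	6	Prevotella jejuni	2.09	88
CST-Pm	6	Rothia mucilaginosa	2.59	79
CST-Pm	6	Staphylococcus epidermidis	0.03	2
CST-Pm	6	Neisseria subflava	2.72	73
CST-Pm	6	Prevotella melaninogenica	18.45	100
CST-Pm	6	Streptococcus mitis	3.12	79
CST-Pm	6	Staphylococcus aureus	0.75	4
CST-Pm	6	Haemophilus influenzae	0.07	6
CST-Pm	6	Prevotella histicola	4.2	71
CST-Pm	6	Pseudomonas aeruginosa	0.03	2
CST-Pm	6	Tetrasphaera japonica	0.42	12
CST-Pm	6	Corynebacterium propinquum	0	0
CST-Sm	6	Streptococcus salivarius	1.56	60
CST-Sm	6	Prevotella jejuni	1.02	28
CST-Sm	6	Rothia mucilaginosa	2.22	74
CST-Sm	6	Staphylococcus epidermidis	0.31	4
CST-Sm	6	Neisseria subflava	1.54	40
CST-Sm	6	Prevotella melaninogenica	2.38	70
CST-Sm	6	Streptococcus mitis	22.59	100
CST-Sm	6	Staphylococcus aureus	0.03	4
CST-Sm	6	Haemophilus influenzae	1.13	30
CST-Sm	6	Prevotella histicola	0.86	28
CST-Sm	6	Pseudomonas aeruginosa	0	0
CST-Sm	6	Tetrasphaera japonica	0.11	10
CST-Sm	6	Corynebacterium propinquum	0	0
CST-Sa	6	Streptococcus salivarius	1.14	33
CST-Sa	6	Prevotella jejuni	0.1	6
CST-Sa	6	Rothia mucilaginosa	1.44	38
CST-Sa	6	Staphylococcus epidermidis	1.33	25
CST-Sa	6	Neisseria subflava	0.07	4
CST-Sa	6	Prevotella melaninogenica	0.4	19
CST-Sa	6	Streptococcus mitis	1.49	33
CST-Sa	6	Staphylococcus aureus	59.58	100
CST-Sa	6	Haemophilus influenzae	0.29	8
CST-Sa	6	Prevotella histicola	0.42	8
CST-Sa	6	Pseudomonas aeruginosa	2.27	27
CST-Sa	6	Tetrasphaera japonica	0.96	17
CST-Sa	6	Corynebacterium propinquum	0.43	4
CST-Hi	3	Streptococcus salivarius	2.56	59
CST-Hi	3	Prevotella jejuni	0.59	31
CST-Hi	3	Rothia mucilaginosa	1.2	45
CST-Hi	3	Staphylococcus epidermidis	1.64	17
CST-Hi	3	Neisseria subflava	0.53	24
CST-Hi	3	Prevotella melaninogenica	0.91	48
CST-Hi	3	Streptococcus mitis	2.93	59
CST-Hi	3	Staphylococcus aureus	0.85	7
CST-Hi	3	Haemophilus influenzae	51.04	100
CST-Hi	3	Prevotella histicola	1.85	38
CST-Hi	3	Pseudomonas aeruginosa	0	0
CST-Hi	3	Tetrasphaera japonica	0.74	31
CST-Hi	3	Corynebacterium propinquum	0.35	3
CST-Ph	3	Streptococcus salivarius	2.93	70
CST-Ph	3	Prevotella jejuni	2.79	74
CST-Ph	3	Rothia mucilaginosa	1.76	74
CST-Ph	3	Staphylococcus epidermidis	0.05	4
CST-Ph	3	Neisseria subflava	1.15	44
CST-Ph	3	Prevotella melaninogenica	5.99	93
CST-Ph	3	Streptococcus mitis	3.1	74
CST-Ph	3	Staphylococcus aureus	0.07	4
CST-Ph	3	Haemophilus influenzae	0.15	4
CST-Ph	3	Prevotella histicola	16.42	100
CST-Ph	3	Pseudomonas aeruginosa	0.06	4
CST-Ph	3	Tetrasphaera japonica	0.18	15
CST-Ph	3	Corynebacterium propinquum	0	0
CST-Pa	2	Streptococcus salivarius	1.28	24
CST-Pa	2	Prevotella jejuni	0.41	19
CST-Pa	2	Rothia mucilaginosa	1.97	38
CST-Pa	2	Staphylococcus epidermidis	0	0
CST-Pa	2	Neisseria subflava	0	0
CST-Pa	2	Prevotella melaninogenica	0.56	29
CST-Pa	2	Streptococcus mitis	0.8	29
CST-Pa	2	Staphylococcus aureus	2.14	24
CST-Pa	2	Haemophilus influenzae	0	0
CST-Pa	2	Prevotella histicola	0.63	24
CST-Pa	2	Pseudomonas aeruginosa	55.84	100
CST-Pa	2	Tetrasphaera japonica	2.37	38
CST-Pa	2	Corynebacterium propinquum	0	0
CST-Tj	2	Streptococcus salivarius	0	0
CST-Tj	2	Prevotella jejuni	0.84	11
CST-Tj	2	Rothia mucilaginosa	0	0
CST-Tj	2	Staphylococcus epidermidis	0	0
CST-Tj	2	Neisseria subflava	0.25	6
CST-Tj	2	Prevotella melaninogenica	1.94	22
CST-Tj	2	Streptococcus mitis	1.59	11
CST-Tj	2	Staphylococcus aureus	0	0
CST-Tj	2	Haemophilus influenzae	0	0
CST-Tj	2	Prevotella histicola	0	0
CST-Tj	2	Pseudomonas aeruginosa	0.15	6
CST-Tj	2	Tetrasphaera japonica	41.09	100
CST-Tj	2	Corynebacterium propinquum	0	0
CST-Cp	1	Streptococcus salivarius	0.42	13
CST-Cp	1	Prevotella jejuni	0	0
CST-Cp	1	Rothia mucilaginosa	0.08	13
CST-Cp	1	Staphylococcus epidermidis	2.04	38
CST-Cp	1	Neisseria subflava	1.69	25
CST-Cp	1	Prevotella melaninogenica	0	0
CST-Cp	1	Streptococcus mitis	0	0
CST-Cp	1	Staphylococcus aureus	2.63	25
CST-Cp	1	Haemophilus influenzae	1.42	13
CST-Cp	1	Prevotella histicola	0	0
CST-Cp	1	Pseudomonas aeruginosa	0	0
CST-Cp	1	Tetrasphaera japonica	4.24	63
CST-Cp	1	Corynebacterium propinquum	50.97	100
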