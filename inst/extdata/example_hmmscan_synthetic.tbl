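#                                                               --- full sequence ---- --- best 1 domain ---- --- domain number estimation ----
# target name        accession   query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target
#------------------- ----------  -------------------- ---------- --------- ------ ----- --------- ------ ----- ---- --- --- --- --- --- --- --- ---------------------
7tm_1                PF00001.21  prot_00001           -            1.2e-45  152.3   0.1   2.1e-44  148.2   0.1  1.9   2   0   0   2   2   2   2 7 transmembrane receptor (rhodopsin family)
Response_reg         PF00072.24  prot_00002           -            3.4e-30  103.7   0.0   5.1e-30  103.1   0.0  1.3   1   0   0   1   1   1   1 Response regulator receiver domain
Response_reg         PF00072.20  prot_00017           -            8.8e-28   95.9   0.0   1.3e-27   95.4   0.0  1.2   1   0   0   1   1   1   1 Response regulator receiver domain
Pkinase_Tyr          PF07714.17  prot_00031           -            6.6e-21   73.5   0.0   9.9e-21   72.9   0.0  1.2   1   0   0   1   1   1   1 Protein tyrosine kinase
7tm_1                PF00001.19  prot_00044           -            4.4e-12   44.6   0.2   8.8e-12   43.6   0.2  1.5   1   1   0   1   1   1   1 7 transmembrane receptor (rhodopsin family)
ADH_zinc_N           PF13561.6   prot_00058           -            1.1e-33  115.6   0.0   1.6e-33  115.1   0.0  1.2   1   0   0   1   1   1   1 Enoyl-(Acyl carrier protein) reductase
#
# Program:         hmmscan
# Version:         3.4 (synthetic example output for documentation)
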