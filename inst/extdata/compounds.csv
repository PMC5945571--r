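# Curated 50-compound essential-oil terpene/terpenoid library with larvicidal
# LC50 fixtures (ug/mL, 95% CI) against Culex quinquefasciatus III/IV instar
# larvae and pupae, transcribed as printed (including internally inconsistent
# confidence intervals, which the loader flags but does not correct).
# SMILES are curated from the compound names; the source gives only names and
# structure drawings. Isomer-ambiguous names resolved as follows:
#   8  Carvotanacetol      -> 2-methyl-5-isopropylcyclohex-2-en-1-ol
#   23 Hydrocarvone        -> 5-(2-hydroxypropan-2-yl)-2-methylcyclohex-2-en-1-one
#      (hydroxy+ketone pattern backed by printed TPSA 37.3 and MlogP 1.369)
#   24 Hydrodihydrocarvone -> 5-(2-hydroxypropan-2-yl)-2-methylcyclohexan-1-one
#   28 trans-Isopulegone   -> 5-methyl-2-(prop-1-en-2-yl)cyclohexan-1-one;
#      printed Ui/MlogP imply a single multiple bond, so the drawn source
#      structure differs; row 28 is never a computed-descriptor anchor
#   37 Phellandrene        -> alpha-phellandrene
#   41 Rotundifolone       -> piperitenone oxide
#   47 beta-Terpineol      -> 1-methyl-4-(prop-1-en-2-yl)cyclohexan-1-ol
#   48 gamma-Terpineol     -> 1-methyl-4-(propan-2-ylidene)cyclohexan-1-ol
# lc50_pupae_censored marks "> 2000" entries (no point estimate printed).
id,name,smiles,class,lc50_iii,lc50_iii_lo,lc50_iii_hi,lc50_iv,lc50_iv_lo,lc50_iv_hi,lc50_pupae,lc50_pupae_lo,lc50_pupae_hi,lc50_pupae_censored
1,p-Anisaldehyde,COc1ccc(C=O)cc1,Benzaldehyde,18.0,15.5,20.4,18.8,16.9,20.6,96.4,92.5,100.2,FALSE
2,Camphor,CC1(C)C2CCC1(C)C(=O)C2,Bicyclic monoterpenoid,22.3,21.6,23.9,25.8,23.6,27.9,245.1,234.6,255.5,FALSE
3,3-Carene,CC1=CCC2C(C1)C2(C)C,Bicyclic monoterpene,24.7,23.7,25.7,25.5,24.3,26.7,105.5,101.8,109.1,FALSE
4,Carvacrol,Cc1ccc(C(C)C)cc1O,Cyclic monoterpenoid,5.5,5.28,5.72,7.7,7.3,8.1,53.2,51.8,54.5,FALSE
5,Carveol,CC1=CCC(C(=C)C)CC1O,Cyclic monoterpenoid,103.0,99.4,109.9,104.6,102.0,107.2,249.0,241.8,256.1,FALSE
6,Carvomenthol,CC1CCC(C(C)C)CC1O,Cyclic monoterpenoid,198.2,183.69,212.71,219.8,206.6,232.9,452.2,435.2,469.1,FALSE
7,(+)-Carvone,CC1=CCC(C(=C)C)CC1=O,Cyclic monoterpenoid,150.2,149.0,151.4,150.2,145.5,154.8,500.6,495.0,506.1,FALSE
8,Carvotanacetol,CC1=CCC(C(C)C)CC1O,Cyclic monoterpenoid,152.3,148.2,156.8,198.3,192.1,204.44,245.1,238.1,252.0,FALSE
9,beta-Caryophyllene,CC1=CCCC(=C)C2CC(C)(C)C2CC1,Bicyclic sesquiterpene,45.6,43.8,47.2,47.7,42.2,52.9,222.3,216.8,27.7,FALSE
10,Citronellal,CC(CCC=C(C)C)CC=O,Acyclic monoterpenoid,105.3,98.3,102.3,124.9,123.2,125.6,549.2,557.35,565.5,FALSE
11,beta-Citronellol,CC(CCC=C(C)C)CCO,Acyclic monoterpenoid,90.4,88.9,91.9,94.8,93.4,95.2,203.1,198.44,207.76,FALSE
12,m-Cresol,Cc1cccc(O)c1,Phenolic derivative,60.0,58.8,61.2,60.6,59.3,61.9,107.7,104.94,110.4,FALSE
13,o-Cresol,Cc1ccccc1O,Phenolic derivative,54.8,53.6,56.0,54.4,53.8,54.0,105.6,103.4,107.7,FALSE
14,Cuminaldehyde,CC(C)c1ccc(C=O)cc1,Benzaldehyde,23.0,22.0,24.0,23.9,22.0,25.8,95.4,91.1,99.6,FALSE
15,p-Cymene,CC(C)c1ccc(C)cc1,Cyclic monoterpene,23.1,22.3,24.9,24.0,23.8,26.2,306.3,298.4,314.1,FALSE
16,trans-Dihydrocarvone,CC1CCC(C(=C)C)CC1=O,Cyclic monoterpene,345.0,340.8,350.1,361.3,346.2,366.4,708.6,698.1,719.1,FALSE
17,"3,4-Dimethylcumene",Cc1ccc(C(C)C)cc1C,Phenolic derivative,35.6,33.5,37.7,47.7,46.2,49.2,105.5,101.9,109.1,FALSE
18,Eucalyptol,CC12CCC(CC1)C(C)(C)O2,Bicyclic monoterpenoid,48.0,47.9,49.1,44.4,43.3,45.5,92.9,86.2,99.6,FALSE
19,Geranial,CC(C)=CCCC(C)=CC=O,Acyclic monoterpenoid,52.2,51.1,53.3,53.4,49.9,56.8,193.9,186.8,200.9,FALSE
20,Geraniol,CC(C)=CCCC(C)=CCO,Acyclic monoterpenoid,20.4,19.78,21.02,20.4,19.4,21.3,104.6,101.9,107.2,FALSE
21,Germacrene-D,CC1=CCCC(=C)C=CC(C(C)C)CC1,Sesquiterpene,45.4,44.3,46.6,45.6,46.71,47.49,229.0,222.7,235.2,FALSE
22,alpha-Humulene,CC1=CCC(C)(C)C=CCC(C)=CCC1,Bicyclic sesquiterpene,100.5,98.2,102.7,101.8,100.0,103.5,508.3,497.17,519.43,FALSE
23,Hydrocarvone,CC1=CCC(C(C)(C)O)CC1=O,Cyclic monoterpene,1351.6,1228.68,1474.5,1470.9,1347.9,1592.9,NA,NA,NA,TRUE
24,Hydrodihydrocarvone,CC1CCC(C(C)(C)O)CC1=O,Cyclic monoterpene,1416.5,1152.4,1680.1,1628.2,1364.6,1889.3,NA,NA,NA,TRUE
25,3-Isopropylphenol,CC(C)c1cccc(O)c1,Cyclic monoterpene,21.3,20.9,21.6,23.1,21.2,24.9,100.2,96.4,104.4,FALSE
26,Isoborneol,CC1(C)C2CCC1(C)C(O)C2,Bicyclic monoterpenoid,91.9,89.7,94.0,97.1,94.1,100.1,206.1,199.7,213.5,FALSE
27,Isopulegol,CC1CCC(C(=C)C)C(O)C1,Cyclic monoterpene,247.4,234.4,250.9,297.3,290.2,304.3,610.8,604.6,616.9,FALSE
28,trans-Isopulegone,CC1CCC(C(=C)C)C(=O)C1,Cyclic monoterpene,529.1,510.1,537.1,538.8,530.7,546.8,908.6,896.2,920.9,FALSE
29,Lavandulol,CC(C)=CCC(CO)C(C)=C,Acyclic monoterpenoid,52.2,51.0,53.3,56.5,53.3,59.9,238.7,224.6,252.7,FALSE
30,Limonene,CC1=CCC(CC1)C(C)=C,Cyclic monoterpene,24.2,23.4,24.9,27.3,23.3,28.2,98.4,95.4,101.4,FALSE
31,Linalool,CC(C)=CCCC(C)(O)C=C,Acyclic monoterpenoid,26.8,26.0,27.5,30.7,29.7,31.6,249.0,241.8,256.1,FALSE
32,Menthol,CC1CCC(C(C)C)C(O)C1,Cyclic monoterpenoid,443.6,432.3,443.2,404.1,381.1,427.0,529.1,521.0,537.1,FALSE
33,Menthone,CC1CCC(C(C)C)C(=O)C1,Cyclic monoterpenoid,500.6,495.0,506.1,508.9,500.8,516.9,878.5,867.4,889.5,FALSE
34,Myrcene,CC(=CCCC(=C)C=C)C,Acyclic monoterpene,19.5,18.5,20.4,19.1,18.0,20.2,31.8,30.2,33.2,FALSE
35,Neoisopulegol,CC1CCC(C(=C)C)C(O)C1,Cyclic monoterpenoid,458.4,450.2,466.6,554.2,545.6,562.7,908.6,896.2,920.9,FALSE
36,(-)-Perillaldehyde,CC(=C)C1CCC(=CC1)C=O,Cyclic monoterpenoid,95.9,94.8,97.0,115.8,113.0,118.6,429.1,422.9,435.22,FALSE
37,Phellandrene,CC1=CCC(C(C)C)C=C1,Cyclic monoterpene,490.7,483.1,498.2,554.3,545.8,563.0,908.6,896.3,920.9,FALSE
38,alpha-Pinene,CC1=CCC2CC1C2(C)C,Bicyclic monoterpene,24.4,23.2,25.5,25.5,22.0,28.97,98.4,95.4,101.4,FALSE
39,beta-Pinene,C=C1CCC2CC1C2(C)C,Bicyclic monoterpene,19.6,18.82,20.38,24.3,22.8,25.7,96.9,89.9,103.9,FALSE
40,(+)-Pulegone,CC1CCC(=C(C)C)C(=O)C1,Cyclic monoterpenoid,168.7,665.8,171.59,188.1,185.29,190.91,496.2,490.4,501.9,FALSE
41,Rotundifolone,CC12CCC(=C(C)C)C(=O)C1O2,Cyclic monoterpenoid,58.9,57.8,59.9,62.5,61.5,63.5,287.4,279.4,295.3,FALSE
42,Sabinene,CC(C)C12CCC(=C)C1C2,Bicyclic monoterpene,53.7,51.9,55.4,59.0,58.3,60.7,268.0,262.5,273.0,FALSE
43,alpha-Terpinene,CC1=CC=C(C(C)C)CC1,Cyclic monoterpene,13.8,12.9,14.7,13.6,12.8,14.3,209.5,204.0,214.9,FALSE
44,gamma-Terpinene,CC1=CCC(C(C)C)=CC1,Cyclic monoterpene,45.4,44.3,46.5,56.8,55.7,57.9,287.4,280.2,294.6,FALSE
45,4-Terpineol,CC1=CCC(O)(C(C)C)CC1,Cyclic monoterpenoid,94.2,91.1,97.3,97.7,90.6,104.8,201.8,195.6,208.0,FALSE
46,alpha-Terpineol,CC1=CCC(CC1)C(C)(C)O,Cyclic monoterpenoid,95.9,93.8,98.0,98.4,95.3,101.4,206.1,198.4,213.7,FALSE
47,beta-Terpineol,CC1(O)CCC(C(=C)C)CC1,Cyclic monoterpenoid,101.3,99.5,103.0,107.4,103.9,110.8,508.3,497.1,519.43,FALSE
48,gamma-Terpineol,CC1(O)CCC(=C(C)C)CC1,Cyclic monoterpenoid,100.5,98.3,102.7,103.6,100.0,109.9,4965.5,4949.1,4981.9,FALSE
49,Terpinolene,CC1=CCC(=C(C)C)CC1,Cyclic monoterpene,20.4,19.6,21.2,18.6,16.9,20.2,107.4,103.9,110.8,FALSE
50,Thymol,Cc1ccc(C(C)C)c(O)c1,Cyclic monoterpenoid,11.1,10.28,11.9,12.2,11.7,12.7,111.4,108.5,114.2,FALSE
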