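"barcode","name","category_id","is_beverage","serving_size","energy_kj_100","protein_g_100","fat_g_100","satfat_g_100","carb_g_100","sugars_g_100","fibre_g_100","sodium_mg_100","fvnl_pct"
"9300608229058","product-0001","cat01",FALSE,78,1773,4.2,4.2,14.6,50.5,52.6,2.9,352,22
"9300600187264","product-0002","cat01",FALSE,37,445,22.9,5,8.1,14.4,46,9.4,812,26
"9300607880793","product-0003","cat03",FALSE,94,2907,7.8,5.1,14.8,29.4,10.9,3.2,598,91
"9300607117882","product-0004","cat01",FALSE,121,2644,7.6,12.1,12.3,41.6,53,10.1,913,16
"9300602346720","product-0005","cat03",FALSE,75,1835,3.5,2.5,8.9,46.9,37.9,6,521,60
"9300603074875","product-0006","cat04",FALSE,28,2844,13.8,22,7.8,52.4,52.2,5.3,819,22
"9300607765069","product-0007","cat01",FALSE,70,882,16.1,4.1,12.2,32.2,46.9,7.6,369,84
"9300600889205","product-0008","cat02",FALSE,80,2098,4.8,26,4.8,33.4,38.7,7.3,144,93
"9300601311514","product-0009","cat04",FALSE,25,3181,22.2,12.7,0.6,9.6,35.6,11,1214,59
"9300607875669","product-0010","cat01",TRUE,150,134,15.8,30.4,1.1,15.9,30.4,5.3,91,91
"9300600225089","product-0011","cat03",FALSE,71,3572,7.8,24.6,10.2,48.5,3.6,2.3,473,73
"9300605938465","product-0012","cat03",FALSE,104,1937,24.1,4.6,5.5,41.2,26,11.4,462,55
"9300600776949","product-0013","cat04",FALSE,25,188,10.2,8.3,4.4,58,30.6,2.3,791,93
"9300600747178","product-0014","cat01",FALSE,32,1048,18.7,6.4,10.5,49.4,30.3,8.2,441,50
"9300603015809","product-0015","cat04",FALSE,134,3354,3.3,14.7,6.5,45.4,37.9,9.4,832,74
"9300604702456","product-0016","cat04",FALSE,21,2304,24.2,7.1,2.5,1.9,20.6,7.7,1482,13
"9300609840993","product-0017","cat02",FALSE,41,1211,21,13.6,10.6,45.1,50.3,4.1,47,65
"9300607488036","product-0018","cat01",TRUE,189,126,14.4,17.4,13.6,53.3,6.5,9,70,8
"9300601623464","product-0019","cat04",FALSE,93,3029,17.8,30.8,12.7,39.4,41.5,5,953,25
"9300608157160","product-0020","cat01",FALSE,64,601,3.7,25.3,9.7,45.5,16.8,8.4,1345,20
"9300605160828","product-0021","cat03",FALSE,111,219,1.5,34.6,7.2,56.1,43.1,8.7,1400,72
"9300600943815","product-0022","cat04",FALSE,57,1539,1.8,2.5,8.8,37.4,49.5,10.3,72,90
"9300607231656","product-0023","cat03",FALSE,85,1490,23.3,5,14.9,7,52.4,3.2,742,34
"9300608057378","product-0024","cat02",FALSE,103,450,13.9,31.2,3.8,5,44.6,10.1,1122,53
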