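cluster,neighborhood,neighborhood_population,neighborhood_case_count,neighborhood_RR,cluster_population,cluster_case_count,cluster_RR,p_value
1,Fort National,11968,6,7.36,593211,101,3.44,< 0.001
1,Poste Marchand,6317,3,6.90,593211,101,3.44,< 0.001
1,Bel Air,14626,6,6.02,593211,101,3.44,< 0.001
1,Saint Gérard,34242,13,5.70,593211,101,3.44,< 0.001
1,Cité de Dieu,22297,8,5.30,593211,101,3.44,< 0.001
1,Cité Numéro Un,20027,7,5.14,593211,101,3.44,< 0.001
1,Saint Antoine,20011,6,4.39,593211,101,3.44,< 0.001
1,Bolosse,41735,11,3.92,593211,101,3.44,< 0.001
1,Morne à Tuf,27762,7,3.70,593211,101,3.44,< 0.001
1,Bois Verna,22514,5,3.24,593211,101,3.44,< 0.001
1,Croix Des Bossales,14780,3,2.94,593211,101,3.44,< 0.001
1,Champs de Mars,23460,4,2.47,593211,101,3.44,< 0.001
1,La Saline,17176,2,1.68,593211,101,3.44,< 0.001
1,Bas Peu De Choses,27838,3,1.56,593211,101,3.44,< 0.001
1,Portail Saint Joseph,29571,3,1.46,593211,101,3.44,< 0.001
1,Portail Leogane,21008,2,1.37,593211,101,3.44,< 0.001
1,Village Démocratie,54673,5,1.32,593211,101,3.44,< 0.001
1,Turgeau,28902,2,0.99,593211,101,3.44,< 0.001
1,Waaf Jérémie,21960,1,0.65,593211,101,3.44,< 0.001
1,Campêche,67825,3,0.63,593211,101,3.44,< 0.001
1,Deprez,24785,1,0.58,593211,101,3.44,< 0.001
1,Baillergeau,11358,0,0.00,593211,101,3.44,< 0.001
1,Saint-Martin,9999,0,0.00,593211,101,3.44,< 0.001
1,Pacot,18378,0,0.00,593211,101,3.44,< 0.001
2,Nerette,16040,19,18.36,16040,19,18.36,< 0.001
3,Bel Air,14626,6,6.02,274495,62,4.00,< 0.001
3,Saint Gérard,34242,13,5.70,274495,62,4.00,< 0.001
3,Cité de Dieu,22297,8,5.30,274495,62,4.00,< 0.001
3,Bolosse,41735,11,3.92,274495,62,4.00,< 0.001
3,Morne à Tuf,27762,7,3.70,274495,62,4.00,< 0.001
3,Croix Des Bossales,14780,3,2.94,274495,62,4.00,< 0.001
3,Champs de Mars,23460,4,2.47,274495,62,4.00,< 0.001
3,La Saline,17176,2,1.68,274495,62,4.00,< 0.001
3,Bas Peu De Choses,27838,3,1.56,274495,62,4.00,< 0.001
3,Portail Saint Joseph,29571,3,1.46,274495,62,4.00,< 0.001
3,Portail Leogane,21008,2,1.37,274495,62,4.00,< 0.001
4,Fort National,11968,6,7.36,58323,22,5.85,< 0.001
4,Poste Marchand,6317,3,6.90,58323,22,5.85,< 0.001
4,Cité Numéro Un,20027,7,5.14,58323,22,5.85,< 0.001
4,Saint Antoine,20011,6,4.39,58323,22,5.85,< 0.001
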