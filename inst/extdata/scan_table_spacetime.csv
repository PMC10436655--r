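cluster,neighborhood,date_start,date_end,neighborhood_population,neighborhood_case_count,neighborhood_RR,cluster_population,cluster_case_count,cluster_RR,p_value
1,Cité de Dieu,21/01/2020,11/05/2020,22297,7,17.68,865530,69,5.67,< 0.001
1,Poste Marchand,21/01/2020,11/05/2020,6317,2,17.48,865530,69,5.67,< 0.001
1,Saint Antoine,21/01/2020,11/05/2020,20011,5,13.96,865530,69,5.67,< 0.001
1,Cité Numéro Un,21/01/2020,11/05/2020,20027,5,13.94,865530,69,5.67,< 0.001
1,Fort National,21/01/2020,11/05/2020,11968,3,13.89,865530,69,5.67,< 0.001
1,Bolosse,21/01/2020,11/05/2020,41735,8,10.82,865530,69,5.67,< 0.001
1,Morne à Tuf,21/01/2020,11/05/2020,27762,4,8.01,865530,69,5.67,< 0.001
1,Croix Des Bossales,21/01/2020,11/05/2020,14780,2,7.47,865530,69,5.67,< 0.001
1,Champs de Mars,21/01/2020,11/05/2020,23460,3,7.08,865530,69,5.67,< 0.001
1,Saint Gérard,21/01/2020,11/05/2020,34242,4,6.49,865530,69,5.67,< 0.001
1,Portail Leogane,21/01/2020,11/05/2020,21008,2,5.25,865530,69,5.67,< 0.001
1,Bois Verna,21/01/2020,11/05/2020,22514,2,4.90,865530,69,5.67,< 0.001
1,Bel Air,21/01/2020,11/05/2020,14626,1,3.76,865530,69,5.67,< 0.001
1,Portail Saint Joseph,21/01/2020,11/05/2020,29571,2,3.73,865530,69,5.67,< 0.001
1,Martissant,21/01/2020,11/05/2020,109011,7,3.59,865530,69,5.67,< 0.001
1,Savane Salée,21/01/2020,11/05/2020,87372,5,3.18,865530,69,5.67,< 0.001
1,Deprez,21/01/2020,11/05/2020,24785,1,2.22,865530,69,5.67,< 0.001
1,Bas Peu De Choses,21/01/2020,11/05/2020,27838,1,1.97,865530,69,5.67,< 0.001
1,Turgeau,21/01/2020,11/05/2020,28902,1,1.90,865530,69,5.67,< 0.001
1,Cité L'Eternel,21/01/2020,11/05/2020,31175,1,1.76,865530,69,5.67,< 0.001
1,Cité Brisson,21/01/2020,11/05/2020,35411,1,1.55,865530,69,5.67,< 0.001
1,Village Démocratie,21/01/2020,11/05/2020,54673,1,1.00,865530,69,5.67,< 0.001
1,Campêche,21/01/2020,11/05/2020,67825,1,0.81,865530,69,5.67,< 0.001
1,Waaf Jérémie,21/01/2020,11/05/2020,21960,0,0.00,865530,69,5.67,< 0.001
1,La Saline,21/01/2020,11/05/2020,17176,0,0.00,865530,69,5.67,< 0.001
1,Saint-Martin,21/01/2020,11/05/2020,9999,0,0.00,865530,69,5.67,< 0.001
1,Chancerelles,21/01/2020,11/05/2020,27727,0,0.00,865530,69,5.67,< 0.001
1,Baillergeau,21/01/2020,11/05/2020,11358,0,0.00,865530,69,5.67,< 0.001
2,Nerette,02/02/2020,27/08/2020,16040,13,25.19,16040,13,25.19,< 0.001
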