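name,mean_1,sem_1,mean_2,sem_2
of_pct_time_central_zone,21.15,2.17,15.01,2.28
of_pct_time_corners,35.85,1.67,42.80,4.70
of_n_central_crossings,9.00,1.11,8.42,1.42
of_total_distance_m,39.26,3.03,42.76,4.64
of_avg_speed_m_s,0.13,0.01,0.14,0.01
no_time_novel_object_s,21.74,3.66,7.86,2.75
no_n_entries_central_zone,7.50,0.89,3.00,0.99
no_pct_time_central_zone,28.81,4.82,13.28,3.34
no_pct_time_corners,37.36,5.53,60.08,7.05
no_total_distance_m,38.45,4.09,33.85,6.48
no_avg_speed_m_s,0.12,0.01,0.11,0.02
ld_n_transitions,30.83,2.83,18.75,2.25
ld_time_light_box_s,314.6,17.25,247.1,33.65
ld_latency_to_dark_s,17.32,2.91,44.89,11.61
si_ri_session1,0.87,0.02,0.75,0.03
si_time_partner1_s1_s,210.2,14.27,146.2,5.13
si_time_empty_cup_s,30.12,4.75,50.4,7.54
si_ri_session2,0.63,0.03,0.44,0.03
si_time_partner2_s2_s,129.2,18.68,96.36,9.55
si_time_partner1_s2_s,69.59,6.34,121.2,10.68
nlr_ri,0.72,0.05,0.47,0.04
nlr_time_moved_object_s,16.39,1.85,15.22,2.45
nlr_time_familiar_object_s,6.71,1.49,21.99,4.78
nor_ri,0.81,0.03,0.51,0.03
nor_time_new_object_s,34.84,4.56,15.22,1.97
nor_time_familiar_object_s,8.43,1.59,14.62,2.29
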