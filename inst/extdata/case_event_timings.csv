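event_id,am_onset_s,dh_onset_s,consensus_onset_s,eeg_duration_s,label,time_to_hbt_max_s,time_max_to_min_s,time_min_to_recovery_s,dot_event_duration_s
1,136,141,138.5,60,seizure,12.5,116,123,251.5
2,692,694,693,50,seizure,15,128,115,258
3,1442,1443,1442.5,50,seizure,10.5,124,112,246.5
4,1920,1923,1921.5,40,seizure,3.5,111,189,192.5
5,2384,2386,2385,60,seizure,14,119,NA,NA
6,2539,NA,2539,30,possible-seizure,6,128,42,172
7,2780,2793,2786.5,90,seizure,46.5,198,142,386.5
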