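subject_id,study,age_at_first_seizure,sex,aetiology,fdr_epilepsy,sleep_only,eeg,imaging,treatment,time,event
MESS-000001,MESS,67.1,male,not_remote_symptomatic,no,no,not_indicated,normal,delayed,20.88,1
MESS-000002,MESS,23.1,male,not_remote_symptomatic,no,no,not_indicated,abnormal,delayed,67.15,1
MESS-000003,MESS,98.1,female,not_remote_symptomatic,no,no,abnormal,normal,delayed,15.15,1
MESS-000004,MESS,16,male,remote_symptomatic,no,no,abnormal,not_indicated,delayed,0.37,1
MESS-000005,MESS,25.1,female,not_remote_symptomatic,no,no,normal,normal,delayed,7.74,1
MESS-000006,MESS,46.7,male,remote_symptomatic,no,no,abnormal,not_indicated,delayed,0.59,1
MESS-000007,MESS,16,female,remote_symptomatic,no,no,abnormal,normal,delayed,16.06,0
MESS-000008,MESS,19.4,male,not_remote_symptomatic,no,no,normal,abnormal,immediate,10.28,1
MESS-000009,MESS,24.9,male,not_remote_symptomatic,no,no,abnormal,normal,delayed,13.89,1
MESS-000010,MESS,23.5,male,not_remote_symptomatic,no,no,abnormal,abnormal,immediate,0.36,1
MESS-000011,MESS,32.6,male,remote_symptomatic,no,no,normal,not_indicated,delayed,22.22,1
MESS-000012,MESS,30.1,male,remote_symptomatic,no,no,normal,normal,immediate,34.78,0
MESS-000013,MESS,22.5,male,not_remote_symptomatic,no,yes,normal,abnormal,delayed,5.92,1
MESS-000014,MESS,74,male,remote_symptomatic,yes,no,abnormal,normal,delayed,25.8,1
MESS-000015,MESS,16,female,not_remote_symptomatic,no,no,normal,normal,immediate,2.68,1
MESS-000016,MESS,25.3,male,not_remote_symptomatic,yes,no,not_indicated,normal,immediate,4.67,1
MESS-000017,MESS,59.7,male,remote_symptomatic,no,no,abnormal,normal,immediate,3.37,1
MESS-000018,MESS,33.6,male,not_remote_symptomatic,no,yes,normal,normal,immediate,8.65,1
MESS-000019,MESS,31.3,female,not_remote_symptomatic,no,no,normal,normal,immediate,8.93,1
MESS-000020,MESS,41.8,male,remote_symptomatic,no,no,normal,normal,immediate,33.5,1
MESS-000021,MESS,38.1,male,not_remote_symptomatic,no,no,normal,normal,immediate,22.28,1
MESS-000022,MESS,30.2,female,not_remote_symptomatic,no,no,normal,normal,immediate,5.51,1
MESS-000023,MESS,51.3,male,remote_symptomatic,no,no,abnormal,normal,delayed,7.57,1
MESS-000024,MESS,41.4,female,remote_symptomatic,no,no,abnormal,normal,immediate,11.57,1
MESS-000025,MESS,28.5,female,not_remote_symptomatic,no,no,normal,abnormal,immediate,15.62,1
MESS-000026,MESS,16,male,not_remote_symptomatic,yes,no,abnormal,normal,immediate,65.88,0
MESS-000027,MESS,22.9,male,not_remote_symptomatic,no,yes,normal,normal,delayed,24.9,1
MESS-000028,MESS,16.4,male,not_remote_symptomatic,no,no,abnormal,normal,delayed,7.73,1
MESS-000029,MESS,16,male,not_remote_symptomatic,no,yes,normal,normal,immediate,8.78,0
MESS-000030,MESS,22.7,male,not_remote_symptomatic,no,no,normal,normal,delayed,37.32,1
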