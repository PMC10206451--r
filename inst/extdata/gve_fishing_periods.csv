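year,wolf_id,pack,social_status,sex,collar_fix_interval,waterway,period_start,period_end,defined_by
2017,V034,Bowman Bay,breeding,male,12 h,Irwin Creek,2017-04-17,2017-05-17,prior study
2017,V046,Bowman Bay,subordinate,male,20 min,Irwin Creek,2017-04-21,2017-05-18,prior study
2018,V060,Bowman Bay,subordinate,female,12 h,Irwin Creek,2018-05-12,2018-05-18,remote camera
2018,V062,Bowman Bay,subordinate,male,20 min,Irwin Creek,2018-05-09,2018-05-25,clusters
2018,V067,Bowman Bay,subordinate,female,collar failed,Irwin Creek,,,
2018,uncollared,unknown,unknown,unknown,,Irwin Creek,2018-05-07,2018-05-16,remote camera
2019,V034,Bowman Bay,breeding,male,,Irwin Creek,2019-05-04,2019-05-21,remote camera
2019,uncollared,unknown,unknown,unknown,,Irwin Creek,2019-04-29,2019-05-21,remote camera
2020,V077,Paradise,breeding,male,20 min,Ash River,2020-05-19,2020-05-29,clusters
2020,V089,Lone Wolf,lone,male,20 min,Ash River,2020-05-20,2020-05-28,camera collar
2021,V071,Lightfoot,breeding,male,20 min,Daley Creek,2021-04-24,2021-05-17,clusters
2021,V094,Half-Moon,breeding,male,20 min,Irwin Creek,2021-05-02,2021-05-09,clusters
2021,O0C,Windsong,subordinate,male,20 min,Ash River & Black Duck,2021-05-26,2021-07-07,clusters
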