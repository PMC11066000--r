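animal_id,group,severity,event_day,event_kind,exclusion_reason
X01,sah,NA,NA,NA,tumor
X02,sah,NA,0,death,intraop_death
X03,sah,NA,NA,NA,filament_suboptimal
X04,sah,NA,NA,NA,filament_suboptimal
X05,sah,NA,1,death,died_before_first_score
X06,sah,NA,1,death,died_before_first_score
X07,sah,NA,1,death,died_before_first_score
X08,sah,NA,1,death,died_before_first_score
X09,sah,NA,NA,NA,missing_day1_data
X10,sah,NA,NA,NA,missing_day1_data
X11,sah,NA,NA,NA,missing_day1_data
S01,sah,severe,2,death,NA
S02,sah,severe,2,death,NA
S03,sah,severe,2,humane_endpoint,NA
S04,sah,severe,3,death,NA
S05,sah,severe,4,death,NA
S06,sah,severe,4,death,NA
M01,sah,moderate,3,scheduled_autopsy,NA
M02,sah,moderate,3,scheduled_autopsy,NA
M03,sah,moderate,3,scheduled_autopsy,NA
M04,sah,moderate,3,scheduled_autopsy,NA
M05,sah,moderate,3,scheduled_autopsy,NA
M06,sah,moderate,4,death,NA
M07,sah,moderate,4,humane_endpoint,NA
M08,sah,moderate,7,scheduled_autopsy,NA
M09,sah,moderate,7,scheduled_autopsy,NA
M10,sah,moderate,7,scheduled_autopsy,NA
M11,sah,moderate,7,scheduled_autopsy,NA
M12,sah,moderate,7,scheduled_autopsy,NA
M13,sah,moderate,7,scheduled_autopsy,NA
M14,sah,moderate,7,scheduled_autopsy,NA
M15,sah,moderate,7,scheduled_autopsy,NA
M16,sah,moderate,7,scheduled_autopsy,NA
M17,sah,moderate,7,scheduled_autopsy,NA
M18,sah,moderate,7,scheduled_autopsy,NA
L01,sah,mild,3,scheduled_autopsy,NA
L02,sah,mild,3,scheduled_autopsy,NA
L03,sah,mild,3,scheduled_autopsy,NA
L04,sah,mild,7,scheduled_autopsy,NA
L05,sah,mild,7,scheduled_autopsy,NA
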