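report_id,drug,role,reactions,sex,age_group,continent,year,seriousness
R001,apalutamide,primary suspect,Rash|Fatigue,M,>=75,Americas,2023,none
R002,apalutamide,primary suspect,Rash,male,65-74,Europe,2022,hospitalisation
R003,apalutamide|prednisone,primary suspect|concomitant,Hot flush|Rash pruritic,M,45-64,Asia,2024,none
R004,darolutamide,primary suspect,Fatigue|Nausea,M,>=75,Americas,2023,none
R005,darolutamide,primary suspect,Hepatic function abnormal,M,65-74,Europe,2024,death
R006,enzalutamide,primary suspect,Fatigue|Dizziness|Fall,M,>=75,Americas,2021,hospitalization
R007,enzalutamide,primary suspect,Seizure,M,45-64,Americas,2019,hospitalization
R008,enzalutamide,primary suspect,Fatigue|Death,unknown,Unknown,Americas,2020,death
R009,enzalutamide,primary suspect,Nausea|Diarrhoea,M,18-44,Oceania,2022,none
R010,enzalutamide,secondary suspect,Fatigue,M,>=75,Europe,2018,none
R011,enzalutamide,primary suspect,Hot flush,F,65-74,Africa,,none
R012,bicalutamide,primary suspect,Gynaecomastia,M,45-64,Europe,2016,none
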