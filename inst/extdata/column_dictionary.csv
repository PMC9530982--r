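table,column,type,description
participants,participant_id,string,Unique opaque participant token
participants,family_name_kanji,string,Family name in kanji
participants,given_name_kanji,string,Given name in kanji
participants,family_name_kana,string,Family name in hiragana
participants,given_name_kana,string,Given name in hiragana
participants,sex,string,male or female
participants,age,integer,Age in years (65 or older)
participants,district_id,string,Residential district (coarser than address)
participants,address_id,string,Residential address (unique per household)
participants,household_id,string,Household identifier
participants,marital_satisfaction,integer,"10-point Likert; higher = more dissatisfied by default; NA allowed"
participants,reports_any_confidant,logical,Whether the respondent reports having any confidant; NA allowed
participants,education_band,string,"One of <6, 6-9, 10-12, 13+, other"
participants,gds_01..gds_15,string,"GDS-15 item responses, yes/no; NA allowed"
participants,smc_1..smc_4,integer,"Subjective memory complaint frequency items, 1-7"
participants,smc_severe,integer,Severe memory-problem indicator (metadata only)
participants,tmig_01..tmig_13,integer,"TMIG Index of Competence items, 0/1; NA allowed"
household_members,participant_id,string,Respondent who listed this co-resident
household_members,family_name_kanji,string,Member family name in kanji
household_members,given_name_kanji,string,Member given name in kanji
household_members,family_name_kana,string,Member family name in hiragana
household_members,given_name_kana,string,Member given name in hiragana
household_members,sex,string,male or female
household_members,age,integer,Member age in years
household_members,relationship,string,Relationship to the respondent
nominations,nominator_id,string,Participant who named this community confidant
nominations,family_name_kanji,string,Nominated family name in kanji (may be blank)
nominations,given_name_kanji,string,Nominated given name in kanji (may be blank)
nominations,family_name_kana,string,Nominated family name in hiragana (may be blank)
nominations,given_name_kana,string,Nominated given name in hiragana (may be blank)
edges,source,string,Participant who regards the target as a confidant
edges,target,string,The confidant
edges,provenance,string,household or community
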