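feature,category,source,engineering
hr_mean,heart rate,wearable,data-driven
hr_sd,heart rate,wearable,data-driven
hr_min,heart rate,wearable,data-driven
hr_max,heart rate,wearable,data-driven
hr_q1,heart rate,wearable,data-driven
hr_q3,heart rate,wearable,data-driven
hr_skew,heart rate,wearable,data-driven
acc_mean,activity,wearable,data-driven
acc_sd,activity,wearable,data-driven
acc_min,activity,wearable,data-driven
acc_max,activity,wearable,data-driven
acc_q1,activity,wearable,data-driven
acc_q3,activity,wearable,data-driven
acc_skew,activity,wearable,data-driven
eda_mean,electrodermal activity,wearable,data-driven
eda_sd,electrodermal activity,wearable,data-driven
eda_min,electrodermal activity,wearable,data-driven
eda_max,electrodermal activity,wearable,data-driven
eda_q1,electrodermal activity,wearable,data-driven
eda_q3,electrodermal activity,wearable,data-driven
eda_skew,electrodermal activity,wearable,data-driven
temp_mean,temperature,wearable,data-driven
temp_sd,temperature,wearable,data-driven
temp_min,temperature,wearable,data-driven
temp_max,temperature,wearable,data-driven
temp_q1,temperature,wearable,data-driven
temp_q3,temperature,wearable,data-driven
temp_skew,temperature,wearable,data-driven
ibi_mean,stress,wearable,domain-driven
ibi_median,stress,wearable,domain-driven
ibi_max,stress,wearable,domain-driven
ibi_min,stress,wearable,domain-driven
sdnn,stress,wearable,domain-driven
rmssd,stress,wearable,domain-driven
nn50,stress,wearable,domain-driven
pnn50,stress,wearable,domain-driven
eda_peaks,stress,wearable,domain-driven
eda_peaks_total_2h,stress,wearable,domain-driven
eda_peaks_mean_2h,stress,wearable,domain-driven
activity_bout,activity,wearable,domain-driven
activity_bouts_1h,activity,wearable,domain-driven
activity_bouts_24h,activity,wearable,domain-driven
acc_vm_mean_2h,activity,wearable,domain-driven
acc_vm_max_2h,activity,wearable,domain-driven
minutes_from_midnight,circadian rhythm,wearable,domain-driven
hours_from_midnight,circadian rhythm,wearable,domain-driven
wake_time,circadian rhythm,wearable,domain-driven
calories_2h,food,food log,domain-driven
calories_8h,food,food log,domain-driven
calories_24h,food,food log,domain-driven
protein_2h,food,food log,domain-driven
protein_8h,food,food log,domain-driven
protein_24h,food,food log,domain-driven
carbs_2h,food,food log,domain-driven
carbs_8h,food,food log,domain-driven
carbs_24h,food,food log,domain-driven
sugar_2h,food,food log,domain-driven
sugar_8h,food,food log,domain-driven
sugar_24h,food,food log,domain-driven
eating_event,food,food log,domain-driven
eating_count_2h,food,food log,domain-driven
eating_count_8h,food,food log,domain-driven
eating_count_24h,food,food log,domain-driven
eating_mean_2h,food,food log,domain-driven
eating_mean_8h,food,food log,domain-driven
eating_mean_24h,food,food log,domain-driven
sex,biological sex,user input,other
hba1c,HbA1c,user input,other
personalization,personalization,model,other
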