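file,column,type,description
epochs.csv,participant_id,string,participant identifier
epochs.csv,day,integer,study day index (1..n_days)
epochs.csv,minute,integer,minute of day (0-1439); one row per 60-s epoch
epochs.csv,counts,integer,activity counts per minute (cpm); 0 = sleep or device not worn
ema.csv,participant_id,string,participant identifier
ema.csv,day_index,integer,diary day (1..7)
ema.csv,moderate_category,integer,daily moderate-activity response category 1-8 (bins 0-9 ... >=70 min); NA = diary not answered
ema.csv,vigorous_category,integer,daily vigorous-activity response category 1-8; NA = diary not answered
brfss.csv,participant_id,string,participant identifier
brfss.csv,moderate_min_per_day,numeric,usual moderate activity duration (min/day; 5-min grid)
brfss.csv,moderate_times_per_week,integer,usual moderate activity frequency (times/week)
brfss.csv,vigorous_min_per_day,numeric,usual vigorous activity duration (min/day; 5-min grid)
brfss.csv,vigorous_times_per_week,integer,usual vigorous activity frequency (times/week)
ipaq.csv,participant_id,string,participant identifier
ipaq.csv,occ_vigorous_days,integer,occupational vigorous activity (days/week)
ipaq.csv,occ_vigorous_hours,numeric,occupational vigorous activity (h/day; 0.25-h grid)
ipaq.csv,occ_moderate_days,integer,occupational moderate activity (days/week)
ipaq.csv,occ_moderate_hours,numeric,occupational moderate activity (h/day; 0.25-h grid)
ipaq.csv,occ_walk_days,integer,occupational walking (days/week)
ipaq.csv,occ_walk_hours,numeric,occupational walking (h/day; 0.25-h grid)
ipaq.csv,transport_walk_days,integer,transport walking (days/week)
ipaq.csv,transport_walk_hours,numeric,transport walking (h/day; 0.25-h grid)
ipaq.csv,transport_bike_days,integer,transport bicycling (days/week)
ipaq.csv,transport_bike_hours,numeric,transport bicycling (h/day; 0.25-h grid)
ipaq.csv,sit_weekday_h,numeric,sitting on a weekday (h/day; 0.5-h grid)
ipaq.csv,sit_weekend_h,numeric,sitting on a weekend day (h/day; 0.5-h grid)
screen_time.csv,participant_id,string,participant identifier
screen_time.csv,tv_weekday_h,numeric,television on a weekday (h/day; 0.5-h grid)
screen_time.csv,tv_weekend_h,numeric,television on a weekend day (h/day; 0.5-h grid)
screen_time.csv,computer_weekday_h,numeric,computer on a weekday (h/day; 0.5-h grid)
screen_time.csv,computer_weekend_h,numeric,computer on a weekend day (h/day; 0.5-h grid)
truth_daily.csv,participant_id,string,participant identifier
truth_daily.csv,day,integer,study day index
truth_daily.csv,compliant,logical,device worn through the wake period this day
truth_daily.csv,wake_min,integer,wake (potential wear) minutes
truth_daily.csv,true_wear_min,integer,device-frame worn minutes (wake minus nonwear)
truth_daily.csv,true_sedentary_min,integer,worn sedentary minutes (device frame)
truth_daily.csv,true_light_min,integer,worn light-activity minutes (device frame)
truth_daily.csv,true_moderate_min,integer,planted moderate minutes visible to the device
truth_daily.csv,true_vigorous_min,integer,planted vigorous minutes visible to the device
truth_daily.csv,behav_moderate_min,integer,behavioral moderate minutes (what self-reports describe)
truth_daily.csv,behav_vigorous_min,integer,behavioral vigorous minutes
truth_daily.csv,behav_sedentary_min,integer,behavioral sedentary minutes over the wake period
participants.csv,participant_id,string,participant identifier
participants.csv,activity_level,numeric,participant activity multiplier (gamma; mean 1)
participants.csv,brfss_mult,numeric,realized multiplicative reporting bias on BRFSS activity
participants.csv,ipaq_mult,numeric,realized multiplicative reporting bias on IPAQ activity
participants.csv,sitting_mult,numeric,realized factor relating reported sitting to true sedentary time
participants.csv,screen_mult,numeric,realized factor relating reported screen time to true sedentary time
estimates.csv,participant_id,string,participant identifier
estimates.csv,instrument,string,"accelerometer, ema, brfss, ipaq or screen_time"
estimates.csv,intensity,string,"sedentary, moderate, vigorous or mvpa"
estimates.csv,minutes_wk,numeric,estimated minutes/week (NA = instrument missing for participant)
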