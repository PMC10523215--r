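volunteer,device,tib_begin,tib_end,first_sleep,tst,se,latency,waso,awake,light,deep,rem
V1,gold,2022-08-10 20:21:37,2022-08-11 04:58:47,2022-08-10 21:14:07,06:51:30,79.57,00:52:30,00:58:00,01:50:30,05:11:30,01:20:30,00:19:30
V1,watch,2022-08-10 20:21:37,2022-08-11 06:25:00,2022-08-10 21:51:00,08:07:00,80.71,01:29:23,00:27:00,00:27:00,04:25:00,01:22:00,02:20:00
V2,gold,2022-08-16 21:11:45,2022-08-17 04:46:08,2022-08-16 22:48:17,04:48:00,63.38,01:36:32,01:35:30,03:11:30,03:50:30,00:43:30,00:14:00
V2,watch,2022-08-16 21:11:45,2022-08-17 04:48:00,2022-08-16 22:36:00,05:30:00,72.33,01:24:15,00:42:00,00:42:00,02:55:00,00:51:00,01:44:00
V3,gold,2022-06-15 22:52:34,2022-06-16 06:11:14,2022-06-15 23:22:34,06:22:00,87.08,00:30:00,00:28:00,00:58:00,04:34:00,01:29:30,00:18:30
V3,watch,2022-06-15 22:52:34,2022-06-16 06:47:00,2022-06-15 23:42:00,06:05:00,76.93,00:49:26,01:00:00,01:00:00,03:28:00,00:41:00,01:56:00
V4,gold,2022-08-04 21:36:38,2022-08-05 06:00:48,2022-08-04 22:29:38,05:52:00,69.82,00:53:00,01:40:00,02:33:00,04:46:00,00:52:00,00:14:00
V4,watch,2022-08-04 21:36:38,2022-08-05 06:36:00,2022-08-05 00:11:00,05:47:00,64.33,02:34:22,00:38:00,00:38:00,03:50:00,00:32:00,01:25:00
V5,gold,2022-09-21 20:07:38,2022-09-22 03:32:48,2022-09-21 20:35:08,06:06:30,82.33,00:27:30,00:52:30,01:20:00,05:07:30,00:23:00,00:36:00
V5,watch,2022-09-21 20:07:38,2022-09-22 05:11:00,2022-09-21 22:07:00,06:24:00,70.67,01:59:22,00:40:00,00:40:00,03:22:00,01:20:00,01:42:00
V6,gold,2022-08-24 21:53:56,2022-08-25 05:24:33,2022-08-24 22:21:06,06:05:00,81.00,00:27:10,01:03:00,01:30:00,03:48:00,01:12:00,01:05:00
V6,watch,2022-08-24 21:53:56,2022-08-25 05:40:00,2022-08-24 22:07:00,06:38:00,85.40,00:13:04,00:45:00,00:45:00,03:00:00,01:53:00,01:45:00
V7,gold,2022-08-04 21:51:54,2022-08-05 05:23:34,2022-08-04 22:33:54,05:34:00,73.95,00:42:00,01:18:00,02:00:00,04:08:00,01:02:30,00:23:30
V7,watch,2022-08-04 21:51:54,2022-08-05 06:04:00,2022-08-04 23:19:00,05:28:00,66.65,01:27:06,01:17:00,01:17:00,03:10:00,01:01:00,01:17:00
V8,gold,2022-08-24 21:10:57,2022-08-25 06:06:25,2022-08-24 21:36:15,07:51:00,87.96,00:25:18,00:37:00,01:02:00,05:14:30,01:15:00,01:21:30
V8,watch,2022-08-24 21:10:57,2022-08-25 06:15:00,2022-08-24 21:33:00,07:46:00,85.65,00:22:03,00:56:00,00:56:00,03:41:00,01:13:00,02:52:00
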